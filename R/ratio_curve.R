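#' Mono-culture-normalized area versus seeding ratio
#'
#' For a focal clone grown in co-cultures at several seeding ratios, divides
#' its mean invaded area at each ratio by its mean mono-culture area at the
#' same time point (the normalization eliminates shared assay noise when the
#' cultures are run in parallel).  The point (ratio 1, normalized area 1) is
#' appended by construction, and an ordinary quadratic polynomial is fitted
#' across ratios: without interactions the curve decreases as the focal
#' seeding ratio decreases, while a positive received interaction bends it
#' into a parabola with an interior peak above 1.
#'
#' @param co_summaries Data frame of focal-clone co-culture invasion
#'   summaries with columns `ratio` (seeding fraction of the focal clone),
#'   `area` and `time` (one row per replicate/observation).
#' @param mono_summaries Data frame of focal-clone mono-culture summaries
#'   with columns `area` and `time`, at the same time point.
#' @param focal Focal clone label, recorded in the result.
#' @return An object of class `ratio_curve`: a data frame with `ratio` and
#'   `normalized_area`, with the quadratic fit coefficients (intercept,
#'   linear, quadratic) in attribute `coef`.
#' @export
normalized_ratio_curve <- function(co_summaries, mono_summaries,
                                   focal = NA_character_) {
  stopifnot(all(c("ratio", "area") %in% names(co_summaries)),
            "area" %in% names(mono_summaries))
  tt <- unique(c(co_summaries$time, mono_summaries$time))
  tt <- tt[!is.na(tt)]
  if (length(tt) > 1)
    stop("co-culture and mono-culture summaries must share one time point")
  mono_area <- mean(mono_summaries$area)
  if (!is.finite(mono_area) || mono_area <= 0)
    stop("mono-culture reference area must be positive")
  agg <- stats::aggregate(area ~ ratio, data = co_summaries, FUN = mean)
  curve <- data.frame(ratio = c(agg$ratio, 1),
                      normalized_area = c(agg$area / mono_area, 1))
  curve <- curve[order(curve$ratio), ]
  rownames(curve) <- NULL
  deg <- min(2L, nrow(curve) - 1L)   # degrade gracefully below 3 points
  fml <- switch(deg + 1L,
                normalized_area ~ 1,
                normalized_area ~ ratio,
                normalized_area ~ ratio + I(ratio^2))
  fit <- stats::lm(fml, data = curve)
  co <- unname(stats::coef(fit))
  attr(curve, "coef") <- c(co, rep(0, 3 - length(co)))
  attr(curve, "focal") <- focal
  attr(curve, "time") <- if (length(tt)) tt else NA_real_
  class(curve) <- c("ratio_curve", "data.frame")
  curve
}

#' Area under the fitted ratio curve
#'
#' Analytic integral over seeding ratio in `[0, 1]` of the quadratic fitted
#' by [normalized_ratio_curve()].  The AUC grows linearly with the received
#' interaction strength, which makes it the summary statistic for
#' interaction inference: a flat curve at 1 has AUC 1, and stronger positive
#' interactions push it up.
#'
#' @param curve A `ratio_curve`.
#' @return Dimensionless AUC.
#' @export
auc_of_curve <- function(curve) {
  co <- attr(curve, "coef")
  if (is.null(co)) stop("no quadratic fit stored on this curve")
  co[1] + co[2] / 2 + co[3] / 3
}
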