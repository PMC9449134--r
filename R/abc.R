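#' Uniform prior specification
#'
#' Non-informative uniform priors, one `(lo, hi)` pair per parameter.  The
#' bounds should be validated by an exploratory run so that the prior
#' encompasses the posterior; the defaults used throughout the package span
#' the biologically plausible range for glioma spheroids: proliferation
#' 0.05-2 d/day, motility 0-20 x/day and interaction strength -30 to 30
#' x/day.
#'
#' @param ... Named length-2 numeric vectors, e.g.
#'   `prior_spec(proliferation = c(0.05, 2), motility = c(0, 20))`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(...) {
  b <- list(...)
  if (length(b) == 0 || is.null(names(b)) || any(names(b) == ""))
    stop("supply named (lo, hi) bounds")
  for (nm in names(b)) {
    v <- b[[nm]]
    if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2])
      stop(sprintf("prior for '%s' must be finite (lo, hi) with lo < hi", nm))
  }
  structure(b, class = "prior_spec")
}

default_phenotype_prior <- function() {
  prior_spec(proliferation = c(0.05, 2), motility = c(0, 20))
}

default_interaction_prior <- function() {
  prior_spec(interaction = c(-30, 30))
}

#' Draw parameter vectors from a uniform prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @return Data frame with one column per parameter.
#' @export
sample_prior <- function(prior, n) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  as.data.frame(lapply(prior, function(b) stats::runif(n, b[1], b[2])))
}

#' Build a databank of simulations
#'
#' The substrate of rejection ABC: a large table of parameter vectors drawn
#' from the prior together with the summary statistics of one fresh
#' simulation each.  Reproducible given `seed` (each row gets its own
#' derived sub-seed so rows are independent of databank size).
#'
#' @param prior A [prior_spec()].
#' @param forward Function `(theta, seed)` mapping a named parameter list
#'   and an integer seed to a named numeric vector of summary statistics.
#' @param n Number of rows.
#' @param seed Master integer seed.
#' @return An object of class `abc_databank`: a data frame holding the
#'   parameter columns, the summary columns, `replicate` and `seed`;
#'   parameter/summary names are kept in attributes `par_names` and
#'   `sum_names`, the prior in `prior`.
#' @export
build_databank <- function(prior, forward, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  theta <- sample_prior(prior, n)
  row_seeds <- derive_seeds(seed, n)
  sums <- vector("list", n)
  for (i in seq_len(n)) {
    s <- forward(as.list(theta[i, , drop = FALSE]), row_seeds[i])
    if (any(!is.finite(unlist(s))))
      stop(sprintf("forward model returned non-finite summaries at row %d", i))
    sums[[i]] <- as.data.frame(as.list(s))
  }
  sums <- do.call(rbind, sums)
  if (is.null(names(sums)) || any(names(sums) == ""))
    stop("forward model must return a *named* summary vector")
  out <- cbind(theta, sums,
               data.frame(replicate = seq_len(n), seed = row_seeds))
  attr(out, "par_names") <- names(theta)
  attr(out, "sum_names") <- names(sums)
  attr(out, "prior") <- prior
  class(out) <- c("abc_databank", "data.frame")
  out
}

# deterministic per-row seeds below 2^31, independent of n
derive_seeds <- function(master, n, salt = 0L) {
  a <- 1103515245; c0 <- 12345; m <- 2^31 - 1
  s <- (as.numeric(master) %% m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (a * s + c0 + salt * 97) %% m
    out[i] <- s
  }
  as.integer(out %% (2^31 - 2) + 1)
}

#' Weighted Euclidean distance between summary vectors
#'
#' `sqrt(sum_i w_i (obs_i - sim_i)^2)` with weights on the simplex
#' (`w_i >= 0`, `sum w_i = 1`).  Zero iff the vectors agree on every
#' positively weighted coordinate.
#'
#' @param obs,sim Equal-length numeric summary vectors; if both are named,
#'   names must match.
#' @param weights Per-summary weights; normalized to sum to 1.
#' @return Non-negative scalar distance.
#' @examples
#' weighted_distance(c(3, 0), c(1, 0), c(1, 0))  # 2
#' @export
weighted_distance <- function(obs, sim, weights = NULL) {
  obs <- unlist(obs); sim <- unlist(sim)
  if (length(obs) != length(sim)) stop("summary vectors differ in length")
  if (!is.null(names(obs)) && !is.null(names(sim)) &&
      !identical(names(obs), names(sim)))
    stop("summary vector names do not match")
  w <- normalize_weights(weights, length(obs))
  sqrt(sum(w * (obs - sim)^2))
}

normalize_weights <- function(weights, k) {
  if (is.null(weights)) weights <- rep(1, k)
  stopifnot(length(weights) == k, all(weights >= 0))
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  weights / s
}

#' Rejection ABC on a databank
#'
#' Computes the weighted Euclidean distance between the observed summary
#' vector and every databank row and accepts the rows whose distance falls
#' below the threshold; the accepted parameter vectors form the posterior
#' sample.  As the threshold approaches zero (on an ever larger databank)
#' the posterior collapses onto the true parameter value.
#'
#' Summaries are standardized by the databank standard deviation of each
#' summary before weighting, so that weights compare information content
#' rather than units (areas in pixels^2 would otherwise dominate
#' densities).  Disable with `standardize = FALSE` to use raw distances.
#'
#' @param databank An [build_databank()] result.
#' @param obs Named numeric vector of observed summaries (must cover the
#'   databank's summary names).
#' @param weights Per-summary weights (databank summary order); equal by
#'   default.
#' @param epsilon Absolute acceptance threshold; overrides `quantile`.
#' @param quantile Acceptance threshold as a quantile of the databank
#'   distances (default 0.005).
#' @param min_accept Minimum acceptable posterior size; the threshold is
#'   raised to admit at least this many rows, and an error is thrown if the
#'   databank itself is smaller.
#' @param standardize Standardize summaries by databank SD first.
#' @return An object of class `abc_posterior`: the accepted parameter rows,
#'   with attributes `distance` (accepted distances), `epsilon`,
#'   `n_accepted`, `weights` and `prior`.
#' @export
abc_reject <- function(databank, obs, weights = NULL, epsilon = NULL,
                       quantile = 0.005, min_accept = 200,
                       standardize = TRUE) {
  stopifnot(inherits(databank, "abc_databank"), nrow(databank) >= 1)
  sn <- attr(databank, "sum_names")
  pn <- attr(databank, "par_names")
  obs <- unlist(obs)
  if (!all(sn %in% names(obs)))
    stop("observed summaries must include: ", paste(sn, collapse = ", "))
  obs <- obs[sn]
  S <- as.matrix(databank[, sn, drop = FALSE])
  if (standardize) {
    sds <- apply(S, 2, stats::sd)
    sds[!is.finite(sds) | sds <= 0] <- 1
    S <- sweep(S, 2, sds, "/")
    obs <- obs / sds
  }
  w <- normalize_weights(weights, length(sn))
  d <- sqrt(colSums(w * (t(S) - obs)^2))
  if (min_accept > nrow(databank))
    stop(sprintf("databank too small: %d rows < min_accept = %d; enlarge the databank",
                 nrow(databank), min_accept))
  eps <- if (!is.null(epsilon)) epsilon
         else stats::quantile(d, quantile, names = FALSE)
  if (sum(d <= eps) < min_accept)
    eps <- sort(d)[min_accept]   # raise threshold to the configured floor
  keep <- d <= eps
  post <- databank[keep, pn, drop = FALSE]
  rownames(post) <- NULL
  structure(post, class = c("abc_posterior", "data.frame"),
            distance = d[keep], epsilon = eps, n_accepted = sum(keep),
            weights = w, prior = attr(databank, "prior"))
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("ABC posterior: %d accepted (epsilon %.4g)\n",
              attr(x, "n_accepted"), attr(x, "epsilon")))
  print(summary(as.data.frame(x)))
  invisible(x)
}
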