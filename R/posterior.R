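#' Maximum-likelihood truncated-normal fit
#'
#' Fits a normal distribution truncated to `bounds` (typically the prior
#' bounds) to a posterior sample by maximizing the truncated-normal
#' likelihood.  The fitted distribution is what carries a mono-culture
#' posterior forward into co-culture simulations, propagating the
#' uncertainty of the first inference stage instead of a point estimate.
#'
#' @param samples Numeric vector of at least 10 values within `bounds`.
#' @param bounds Length-2 truncation interval `(lower, upper)`.
#' @return An object of class `truncnorm_fit` with `mean`, `sd`, `lower`,
#'   `upper` and the attained `loglik`.
#' @export
fit_truncated_normal <- function(samples, bounds) {
  x <- as.numeric(samples)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  x <- x[x >= bounds[1] & x <= bounds[2]]
  if (length(x) < 10) stop("need at least 10 samples within bounds")
  mu0 <- mean(x)
  sd0 <- max(stats::sd(x), 1e-6 * (bounds[2] - bounds[1]), 1e-12)
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    z <- stats::pnorm(bounds[2], mu, sigma) - stats::pnorm(bounds[1], mu, sigma)
    if (z <= 0) return(1e10)
    -sum(stats::dnorm(x, mu, sigma, log = TRUE)) + length(x) * log(z)
  }
  o <- stats::optim(c(mu0, log(sd0)), nll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  structure(list(mean = o$par[1], sd = exp(o$par[2]),
                 lower = bounds[1], upper = bounds[2],
                 loglik = -o$value),
            class = "truncnorm_fit")
}

#' @export
print.truncnorm_fit <- function(x, ...) {
  cat(sprintf("truncated normal: mean %.4g, sd %.4g on [%.4g, %.4g]\n",
              x$mean, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Sample from a fitted truncated normal
#'
#' Inverse-CDF sampling; all draws lie inside the truncation interval.
#'
#' @param n Number of draws.
#' @param fit A `truncnorm_fit` (or list with `mean`, `sd`, `lower`,
#'   `upper`).
#' @return Numeric vector of length `n`.
#' @export
rtruncnorm_fit <- function(n, fit) {
  plo <- stats::pnorm(fit$lower, fit$mean, fit$sd)
  phi <- stats::pnorm(fit$upper, fit$mean, fit$sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, fit$mean, fit$sd)
  pmin(pmax(q, fit$lower), fit$upper)
}

#' Highest-density interval of a posterior sample
#'
#' The shortest contiguous interval containing `ceiling(level * n)` of the
#' sorted samples — the credible interval in which the true parameter value
#' is expected to lie.
#'
#' @param samples Numeric vector (>= 20 values for a meaningful interval).
#' @param level Credibility level in `(0, 1]`; default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hdi(rnorm(1e4))  # close to c(-1.96, 1.96)
#' @export
hdi <- function(samples, level = 0.95) {
  x <- sort(as.numeric(samples))
  n <- length(x)
  stopifnot(n >= 2, level > 0, level <= 1)
  m <- ceiling(level * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Modal interval of a posterior sample
#'
#' Bounds of the most populated histogram bin, on a grid of width
#' `bin_width` anchored at zero; ties are broken toward the lowest bin.
#' This is how interaction strengths are reported: e.g. a modal interval of
#' (2.5, 3.0) at bin width 0.5.
#'
#' @param samples Numeric vector.
#' @param bin_width Positive bin width (0.5 is used for rates, 1.0 for
#'   interaction strengths).
#' @return Named numeric `c(lower, upper)` of the modal bin.
#' @export
modal_interval <- function(samples, bin_width = 0.5) {
  stopifnot(bin_width > 0, length(samples) >= 1)
  x <- as.numeric(samples)
  b <- floor(x / bin_width)            # grid anchored at 0
  tab <- table(b)
  lev <- as.numeric(names(tab))
  best <- lev[tab == max(tab)]
  lo <- min(best) * bin_width          # ties -> lowest bin
  c(lower = lo, upper = lo + bin_width)
}

#' Credible-interval report for a posterior sample
#'
#' @param samples Numeric posterior sample.
#' @param level HDI level.
#' @param bin_width Modal-interval bin width.
#' @return List with `hdi`, `modal_interval`, `bin_width`, `level`, `n`.
#' @export
credible_report <- function(samples, level = 0.95, bin_width = 0.5) {
  list(hdi = hdi(samples, level),
       modal_interval = modal_interval(samples, bin_width),
       bin_width = bin_width, level = level, n = length(samples))
}
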