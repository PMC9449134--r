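#' Optimize summary-statistic weights with a genetic algorithm
#'
#' Searches the simplex of per-summary weights (`w_i >= 0`, `sum w_i = 1`)
#' for the weighting of the Euclidean ABC distance that best recovers known
#' parameters.  The fitness of a weight vector is the sum, over validation
#' pairs and parameters, of the squared prior-width-normalized distance
#' between the ground truth and the posterior point estimate (the
#' accepted-sample median) obtained with those weights.  Multiple restarts
#' from random starting weights guard against local optima; the equal
#' weight vector is always included in the starting population, so the
#' optimized weights never recover worse than equal weighting on the
#' validation set.
#'
#' @param databank An [build_databank()] result.
#' @param validation List of validation cases, each a list with `theta`
#'   (named true parameter values) and `obs` (named observed summary
#'   vector), generated from simulations with known ground truth.
#' @param population,generations,restarts GA size parameters (defaults 50,
#'   100, 5; reduce for toy problems).
#' @param mutation_sd Gaussian mutation scale (before projection back onto
#'   the simplex).
#' @param tournament Tournament size for parent selection.
#' @param abc_opts List of options forwarded to [abc_reject()] for the
#'   inner posterior evaluations (e.g. `quantile`, `min_accept`).
#' @return Numeric weight vector (summary names attached) summing to 1,
#'   with the attained `fitness` and the equal-weight fitness as
#'   attributes.
#' @export
ga_optimize_weights <- function(databank, validation, population = 50,
                                generations = 100, restarts = 5,
                                mutation_sd = 0.1, tournament = 3,
                                abc_opts = list(quantile = 0.05,
                                                min_accept = 20)) {
  sn <- attr(databank, "sum_names")
  pn <- attr(databank, "par_names")
  k <- length(sn)
  prior <- attr(databank, "prior")
  widths <- vapply(prior, function(b) b[2] - b[1], numeric(1))[pn]
  if (k == 1) {
    w <- stats::setNames(1, sn)
    attr(w, "fitness") <- NA_real_
    return(w)
  }
  stopifnot(length(validation) >= 1)

  fitness <- function(w) {
    err <- 0
    for (v in validation) {
      post <- do.call(abc_reject,
                      c(list(databank = databank, obs = v$obs, weights = w),
                        abc_opts))
      est <- vapply(as.data.frame(post)[pn], stats::median, numeric(1))
      tru <- unlist(v$theta)[pn]
      err <- err + sum(((est - tru) / widths)^2)
    }
    err
  }

  project <- function(w) {              # clip to >= 0, renormalize
    w[w < 0] <- 0
    if (sum(w) <= 0) w <- rep(1, k)
    w / sum(w)
  }
  rand_simplex <- function() project(stats::rexp(k))

  equal_fit <- fitness(rep(1 / k, k))
  best_w <- rep(1 / k, k)
  best_f <- equal_fit

  for (r in seq_len(restarts)) {
    pop <- c(list(rep(1 / k, k)),
             replicate(population - 1, rand_simplex(), simplify = FALSE))
    fit <- vapply(pop, fitness, numeric(1))
    for (g in seq_len(generations)) {
      elite <- which.min(fit)
      newpop <- list(pop[[elite]])
      while (length(newpop) < population) {
        pick <- function() {
          cand <- sample.int(population, tournament)
          pop[[cand[which.min(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        u <- stats::runif(1)
        child <- u * p1 + (1 - u) * p2
        child <- project(child + stats::rnorm(k, 0, mutation_sd))
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness, numeric(1))
    }
    i <- which.min(fit)
    if (fit[i] < best_f) { best_f <- fit[i]; best_w <- pop[[i]] }
  }

  w <- best_w / sum(best_w)
  w[k] <- 1 - sum(w[-k])               # force an exact simplex sum
  w <- stats::setNames(w, sn)
  attr(w, "fitness") <- best_f
  attr(w, "equal_weight_fitness") <- equal_fit
  w
}
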