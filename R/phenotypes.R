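#' Per-clone phenotype parameters
#'
#' A clone's phenotype is described by a proliferation rate (divisions per
#' day, d/day) and a motility rate (cell widths travelled per day, x/day).
#' Cell death is not a free parameter: the death rate is always a fixed
#' fraction of the proliferation rate (10% by default), which allows for
#' cellular turnover while guaranteeing net growth.  The aggression
#' parameter is the maximum Chebyshev distance over which a dividing cell
#' may push neighbouring cells to reach an empty lattice site; aggression 1
#' means divisions only succeed into an empty Moore neighbour.
#'
#' @param proliferation Proliferation rate, divisions per day; must be >= 0.
#' @param motility Base motility rate, cell widths per day; must be >= 0.
#' @param aggression Non-negative integer push distance (lattice units).
#' @param death_fraction Death rate as a fraction of the proliferation rate.
#' @return An object of class `phenotype_params`.
#' @examples
#' phenotype_params(proliferation = 1, motility = 5)
#' @export
phenotype_params <- function(proliferation, motility, aggression = 1L,
                             death_fraction = 0.1) {
  stopifnot(is.numeric(proliferation), length(proliferation) == 1L,
            is.finite(proliferation), proliferation >= 0,
            is.numeric(motility), length(motility) == 1L,
            is.finite(motility), motility >= 0,
            is.numeric(death_fraction), death_fraction >= 0)
  if (!isTRUE(all.equal(aggression, round(aggression))) || aggression < 0)
    stop("`aggression` must be a non-negative integer")
  structure(list(proliferation = as.numeric(proliferation),
                 motility = as.numeric(motility),
                 aggression = as.integer(aggression),
                 death_fraction = as.numeric(death_fraction)),
            class = "phenotype_params")
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf(
    "phenotype: proliferation %.3g d/day, motility %.3g x/day, aggression %d, death = %.0f%% of division\n",
    x$proliferation, x$motility, x$aggression, 100 * x$death_fraction))
  invisible(x)
}

#' Interaction model between two clones
#'
#' Interactions modify the motility of a clone additively, scaled by the
#' current proportion of the other clone: the effective motility of clone i
#' is `M_i = m_i + r_j * I_ij`, where `m_i` is the base motility, `r_j` the
#' proportion of clone j among all cells and `I_ij` the interaction strength
#' received by i from j (x/day per unit proportion).  Negative effective
#' motilities are clamped to zero.  By default proportions are computed over
#' the whole lattice (a global neighbourhood, the long-range signalling
#' regime); a finite `neighborhood` restricts them to a 3D Moore
#' neighbourhood of that radius around each cell.
#'
#' @param strengths 2x2 numeric matrix; entry `[i, j]` is the interaction
#'   received by clone i from clone j.  The diagonal must be zero.
#' @param neighborhood `"global"` (default) or a positive integer Moore
#'   radius for local proportion computation.
#' @return An object of class `interaction_model`.
#' @examples
#' interaction_model(strengths = matrix(c(0, 3, 0, 0), 2, 2, byrow = TRUE))
#' @export
interaction_model <- function(strengths = matrix(0, 2, 2),
                              neighborhood = "global") {
  strengths <- as.matrix(strengths)
  stopifnot(is.numeric(strengths), all(dim(strengths) == c(2L, 2L)),
            all(is.finite(strengths)))
  if (any(diag(strengths) != 0))
    stop("self-interaction (diagonal of `strengths`) must be zero")
  if (identical(neighborhood, "global")) {
    nb <- -1L
  } else {
    stopifnot(is.numeric(neighborhood), length(neighborhood) == 1L,
              neighborhood >= 1)
    nb <- as.integer(neighborhood)
  }
  dimnames(strengths) <- list(receiver = c("A", "B"), source = c("A", "B"))
  structure(list(strengths = strengths, neighborhood = nb),
            class = "interaction_model")
}

#' @export
print.interaction_model <- function(x, ...) {
  nb <- if (x$neighborhood < 0) "global" else x$neighborhood
  cat("interaction model (neighbourhood:", nb, ")\n")
  print(x$strengths)
  invisible(x)
}

#' Simulation configuration
#'
#' @param lattice_edge Sites per axis of the cubic lattice.
#' @param seed_radius Radius (lattice units) of the initial spheroid; every
#'   site within this Euclidean distance of the lattice centre is seeded.
#' @param seeding_ratio Initial fraction of clone A in `[0, 1]`; 1 is a
#'   mono-culture of clone A.
#' @param end_time Simulated end time in days.
#' @param snapshot_interval Interval between 2D-collapsed snapshots, days.
#' @param rng_seed Integer seed; a simulation is bit-reproducible given the
#'   seed and configuration.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(lattice_edge = 120L, seed_radius = 5,
                              seeding_ratio = 1, end_time = 3,
                              snapshot_interval = 1, rng_seed = 1L) {
  stopifnot(lattice_edge >= 3, seed_radius >= 0,
            seeding_ratio >= 0, seeding_ratio <= 1,
            end_time >= 0, snapshot_interval > 0,
            snapshot_interval <= end_time || end_time == 0)
  structure(list(lattice_edge = as.integer(lattice_edge),
                 seed_radius = as.numeric(seed_radius),
                 seeding_ratio = as.numeric(seeding_ratio),
                 end_time = as.numeric(end_time),
                 snapshot_interval = as.numeric(snapshot_interval),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Effective motility of a clone under interaction
#'
#' Implements `M_i = max(0, m_i + sum_j r_j * I_ij)` over the other clones:
#' a clone's motility is shifted by the interaction it receives, scaled by
#' the proportion of the source clone.  In a mono-culture (all other
#' proportions zero) the base motility is returned unchanged.
#'
#' @param clone `"A"` or `"B"` (or 1/2), the receiving clone.
#' @param base Base motility rate, x/day; must be non-negative.
#' @param proportions Named or positional numeric vector of per-clone
#'   proportions (A, B) among living cells; must sum to 1 over clones
#'   present.
#' @param model An [interaction_model()].
#' @return Effective motility in x/day, clamped at zero.
#' @examples
#' m <- interaction_model(matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE))
#' effective_motility("A", 1, c(A = 0.5, B = 0.5), m)  # 1 + 0.5 * 2 = 2
#' @export
effective_motility <- function(clone, base, proportions, model) {
  i <- clone_index(clone)
  stopifnot(is.numeric(base), length(base) == 1L)
  if (base < 0) stop("base motility must be non-negative")
  p <- as.numeric(proportions)
  if (length(p) != 2L) stop("`proportions` must have one entry per clone")
  M <- base
  for (j in seq_len(2L)) if (j != i) M <- M + p[j] * model$strengths[i, j]
  max(0, M)
}

clone_index <- function(clone) {
  if (is.character(clone)) clone <- match(toupper(clone), c("A", "B"))
  if (is.na(clone) || !clone %in% 1:2) stop("clone must be 'A', 'B', 1 or 2")
  as.integer(clone)
}

#' Enumerate SSA event propensities
#'
#' Tabulates, for the current lattice state, the per-cell rate of each
#' process (division at the proliferation rate, movement at the effective
#' motility, death at `death_fraction` times the proliferation rate) and the
#' total event rate that drives the exponential waiting time of the
#' stochastic simulation algorithm.  Proportions for the interaction term
#' are the global clone proportions (the default interaction neighbourhood).
#'
#' @param state A [lattice_state] as returned by [initialize_spheroid()].
#' @param params List of two [phenotype_params()] named `A` and `B` (or a
#'   single set for a mono-culture).
#' @param model An [interaction_model()]; defaults to no interaction.
#' @return A data frame with columns `clone`, `process`, `rate_per_cell`,
#'   `n_cells` and `rate_total`, with the lattice-wide total rate (1/day) in
#'   attribute `total_rate`.
#' @export
enumerate_propensities <- function(state, params, model = interaction_model()) {
  params <- as_clone_params(params)
  n <- as.numeric(state$counts)
  ntot <- sum(n)
  props <- if (ntot > 0) n / ntot else c(0, 0)
  rows <- list()
  for (i in 1:2) {
    ph <- params[[i]]
    M <- effective_motility(i, ph$motility, props, model)
    rows[[i]] <- data.frame(
      clone = c("A", "B")[i],
      process = c("division", "movement", "death"),
      rate_per_cell = c(ph$proliferation, M,
                        ph$death_fraction * ph$proliferation),
      n_cells = n[i])
  }
  out <- do.call(rbind, rows)
  out$rate_total <- out$rate_per_cell * out$n_cells
  attr(out, "total_rate") <- sum(out$rate_total)
  out
}

# normalize user-supplied params to a list of two phenotype_params (A, B)
as_clone_params <- function(params) {
  if (inherits(params, "phenotype_params"))
    return(list(A = params, B = phenotype_params(0, 0)))
  if (is.list(params) && length(params) == 2L &&
      all(vapply(params, inherits, logical(1), "phenotype_params"))) {
    names(params) <- c("A", "B")
    return(params)
  }
  stop("`params` must be a phenotype_params or a list of two (clone A, clone B)")
}
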