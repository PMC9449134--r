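#' @name lattice_state
#' @title 3D lattice state of a spheroid simulation
#' @description A `lattice_state` holds the full 3D occupancy grid (0 empty,
#'   1 clone A, 2 clone B), the per-clone cell counts and the current
#'   simulated time in days.  Counts always equal the grid tallies.
NULL

new_lattice_state <- function(occupancy, time = 0) {
  counts <- c(A = sum(occupancy == 1L), B = sum(occupancy == 2L))
  structure(list(occupancy = occupancy, counts = counts, time = time),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  L <- dim(x$occupancy)[1]
  cat(sprintf("lattice_state: %d^3 lattice, t = %.3g d, %d cells (A: %d, B: %d)\n",
              L, x$time, sum(x$counts), x$counts[["A"]], x$counts[["B"]]))
  invisible(x)
}

#' Seed a spheroid at the lattice centre
#'
#' Occupies every site within Euclidean distance `seed_radius` of the
#' lattice centre (the initial spheroid; radius 5 gives 515 sites), drawing
#' each site's clone identity independently as clone A with probability
#' `seeding_ratio`, clone B otherwise — a well-mixed spheroid.  Clone
#' assignment consumes the current RNG stream; [run_simulation()] seeds it
#' from `config$rng_seed` first.
#'
#' @param config A [simulation_config()].  The seed ball must fit strictly
#'   inside the lattice (not touch the frame), otherwise an error is thrown.
#' @return A [lattice_state] at time 0.
#' @examples
#' st <- initialize_spheroid(simulation_config(lattice_edge = 31))
#' sum(st$counts)  # 515
#' @export
initialize_spheroid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$lattice_edge
  r <- config$seed_radius
  c0 <- floor(L / 2) + 1L
  if (c0 - r <= 1 || c0 + r >= L)
    stop(sprintf(
      "configuration error: seed ball (radius %g) touches the lattice frame (edge %d)",
      r, L))
  ri <- floor(r)
  ax <- (c0 - ri):(c0 + ri)
  g <- expand.grid(x = ax, y = ax, z = ax)
  keep <- (g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2
  g <- g[keep, , drop = FALSE]
  occ <- array(0L, dim = c(L, L, L))
  clone <- ifelse(stats::runif(nrow(g)) < config$seeding_ratio, 1L, 2L)
  occ[cbind(g$x, g$y, g$z)] <- clone
  new_lattice_state(occ, time = 0)
}

#' Collapse a 3D state to per-clone 2D masks
#'
#' Emulates what a microscope sees: for each clone, an `L x L` binary mask
#' whose pixel `(x, y)` is 1 iff at least one cell of that clone exists at
#' that `(x, y)` for any z.
#'
#' @param state A [lattice_state].
#' @return A list with 0/1 integer matrices `A` and `B`.
#' @export
collapse_to_2d <- function(state) {
  occ <- state$occupancy
  L <- dim(occ)[1]
  out <- list()
  for (i in 1:2) {
    m <- matrix(0L, L, L)
    idx <- which(occ == i, arr.ind = TRUE)
    if (nrow(idx) > 0) m[unique(idx[, 1:2, drop = FALSE])] <- 1L
    out[[c("A", "B")[i]]] <- m
  }
  out
}
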