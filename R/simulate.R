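#' Advance a lattice state by Gillespie's stochastic simulation algorithm
#'
#' Repeatedly draws an exponential waiting time from the total event rate,
#' picks a cell and process with probability proportional to its rate, and
#' executes it, until the next event would pass `until`; the state time is
#' then set to `until`.  Blocked moves and divisions consume the SSA event
#' (time advances, state unchanged).  A total rate of zero fast-forwards the
#' clock.  Uses the current R RNG stream, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param state A [lattice_state].
#' @param params A [phenotype_params()] (mono-culture) or list of two.
#' @param model An [interaction_model()].
#' @param until Target time in days; must be `>= state$time`.
#' @param max_events Stop after this many events (default unlimited); useful
#'   for single-event fixtures.
#' @param record_limit Record the first `record_limit` events (clone,
#'   process, waiting time, success) in attribute `log`.
#' @return The advanced [lattice_state], with attributes `tally` (event
#'   counts by type, selected and realized), `n_events` and optionally
#'   `log`.
#' @export
advance <- function(state, params, model = interaction_model(), until,
                    max_events = -1L, record_limit = 0L) {
  stopifnot(inherits(state, "lattice_state"))
  if (until < state$time) stop("`until` must not precede the current time")
  params <- as_clone_params(params)
  L <- dim(state$occupancy)[1]
  res <- cpp_advance(
    state$occupancy, L,
    vapply(params, `[[`, numeric(1), "proliferation"),
    vapply(params, `[[`, numeric(1), "motility"),
    vapply(params, `[[`, integer(1), "aggression"),
    params$A$death_fraction,
    model$strengths, model$neighborhood,
    state$time, until, as.integer(max_events), as.integer(record_limit))
  out <- new_lattice_state(res$occupancy, time = res$time)
  attr(out, "tally") <- res$tally
  attr(out, "n_events") <- res$n_events
  if (res$boundary_contact)
    attr(out, "boundary_contact") <- TRUE
  if (record_limit > 0) attr(out, "log") <- res$log
  out
}

#' Single-event primitives
#'
#' `execute_move()` relocates the cell at `site` to an empty site chosen
#' uniformly among its 26 Moore neighbours (null event if all are blocked);
#' `execute_division()` places a same-clone daughter in an empty Moore
#' neighbour, or — when fully enclosed and `aggression > 1` — pushes the
#' contiguous run of cells along a lattice ray toward a nearest empty site
#' within the aggression distance; `execute_death()` vacates the site
#' immediately.  These are the primitives the SSA loop dispatches; they are
#' exported for inspection and testing.
#'
#' @param state A [lattice_state].
#' @param site Integer `(x, y, z)` coordinates (1-based) of an occupied site.
#' @param aggression Push distance for division.
#' @return The updated [lattice_state] with attribute `success` (FALSE for a
#'   blocked null event).
#' @name event_primitives
NULL

site_linear0 <- function(state, site) {
  L <- dim(state$occupancy)[1]
  stopifnot(length(site) == 3L, all(site >= 1), all(site <= L))
  (site[1] - 1L) + L * ((site[2] - 1L) + L * (site[3] - 1L))
}

wrap_event <- function(state, res) {
  out <- new_lattice_state(res$occupancy, time = state$time)
  attr(out, "success") <- res$success
  out
}

#' @rdname event_primitives
#' @export
execute_move <- function(state, site) {
  L <- dim(state$occupancy)[1]
  wrap_event(state, cpp_execute_move(state$occupancy, L,
                                     site_linear0(state, site)))
}

#' @rdname event_primitives
#' @export
execute_division <- function(state, site, aggression = 1L) {
  L <- dim(state$occupancy)[1]
  wrap_event(state, cpp_execute_division(state$occupancy, L,
                                         site_linear0(state, site),
                                         as.integer(aggression)))
}

#' @rdname event_primitives
#' @export
execute_death <- function(state, site) {
  L <- dim(state$occupancy)[1]
  wrap_event(state, cpp_execute_death(state$occupancy, L,
                                      site_linear0(state, site)))
}

#' Run a full spheroid invasion simulation
#'
#' Seeds a spheroid, advances it by the SSA and collects 2D-collapsed
#' snapshots at `t = 0, snapshot_interval, ..., end_time`.  The RNG is
#' seeded from `config$rng_seed`, so identical configurations yield
#' bit-identical snapshot stacks.  Contact of any cell with the lattice
#' frame (treated as permanently occupied, no flux) triggers a warning,
#' since a trustworthy run should never reach the frame.
#'
#' @inheritParams advance
#' @param config A [simulation_config()].
#' @return An object of class `ca_snapshots`: a list of snapshots, each with
#'   `time` (days), `masks` (per-clone 0/1 matrices, see [collapse_to_2d()])
#'   and `counts`; attributes `tally` (event counts), `seed` and `config`.
#' @examples
#' snaps <- run_simulation(simulation_config(lattice_edge = 40, end_time = 1,
#'                                           rng_seed = 7),
#'                         phenotype_params(1, 2))
#' length(snaps)  # 2: day 0 and day 1
#' @export
run_simulation <- function(config, params, model = interaction_model()) {
  stopifnot(inherits(config, "simulation_config"))
  params <- as_clone_params(params)
  set.seed(config$rng_seed)
  state <- initialize_spheroid(config)
  times <- snapshot_times(config)
  res <- cpp_run(
    state$occupancy, config$lattice_edge,
    vapply(params, `[[`, numeric(1), "proliferation"),
    vapply(params, `[[`, numeric(1), "motility"),
    vapply(params, `[[`, integer(1), "aggression"),
    params$A$death_fraction,
    model$strengths, model$neighborhood,
    0, times, FALSE)
  snaps <- lapply(res$snapshots, function(s) {
    names(s$counts) <- c("A", "B")
    structure(s, class = "ca_snapshot")
  })
  if (res$boundary_contact)
    warning("cells reached the lattice frame; results near the boundary are unreliable")
  structure(snaps, class = "ca_snapshots",
            tally = res$tally, boundary_contact = res$boundary_contact,
            seed = config$rng_seed, config = config)
}

snapshot_times <- function(config) {
  times <- seq(0, config$end_time, by = config$snapshot_interval)
  if (max(times) < config$end_time - 1e-9)
    times <- c(times, config$end_time)
  times
}

#' @export
print.ca_snapshots <- function(x, ...) {
  tl <- attr(x, "tally")
  cat(sprintf("ca_snapshots: %d snapshots, t = %.3g..%.3g d (seed %d)\n",
              length(x), x[[1]]$time, x[[length(x)]]$time, attr(x, "seed")))
  cat(sprintf("  events: %.0f divisions (%.0f realized), %.0f moves (%.0f realized), %.0f deaths\n",
              tl$divisions_selected, tl$divisions_realized,
              tl$moves_selected, tl$moves_realized, tl$deaths))
  cat(sprintf("  final counts: A %d, B %d\n",
              x[[length(x)]]$counts[["A"]], x[[length(x)]]$counts[["B"]]))
  invisible(x)
}
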