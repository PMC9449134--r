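#' Radial occupancy profile of a binary mask
#'
#' Bins mask pixels into concentric annuli around the spheroid centre and
#' reports, per annulus, the fraction of its pixels that are occupied.  This
#' occupancy fraction plays the role of the cellular density `C(r)` at
#' distance `r` from the centre in the travelling-wave fit: it is bounded by
#' 1, matching the logistic wave form.
#'
#' @param mask 0/1 integer (or logical) matrix.
#' @param center Numeric `(x, y)`; defaults to the geometric centre of the
#'   mask frame, which is the lattice centre for simulated masks.  For
#'   experimental stacks, pass the centroid of the day-0 mask.
#' @param bin_width Annulus width in pixels.
#' @return An object of class `radial_profile`: a data frame with
#'   `bin_center` (pixels from centre), `occupancy` (in `[0, 1]`) and
#'   `n_pixels` per annulus, covering the range up to the farthest occupied
#'   pixel; the centre used is stored in attribute `center`.
#' @export
radial_profile <- function(mask, center = NULL, bin_width = 1) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0) stop("empty mask: no occupied pixels")
  stopifnot(bin_width > 0)
  d <- dim(mask)
  if (is.null(center)) center <- c(floor(d[1] / 2) + 1, floor(d[2] / 2) + 1)
  stopifnot(length(center) == 2L,
            center[1] >= 1, center[1] <= d[1],
            center[2] >= 1, center[2] <= d[2])
  xs <- matrix(seq_len(d[1]), d[1], d[2])
  ys <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  r <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  rmax <- max(r[mask == 1])
  bin <- floor(r / bin_width)
  nb <- floor(rmax / bin_width) + 1
  keep <- bin < nb
  tot <- tabulate(bin[keep] + 1L, nbins = nb)
  occ <- tabulate(bin[keep & mask == 1] + 1L, nbins = nb)
  out <- data.frame(bin_center = (seq_len(nb) - 0.5) * bin_width,
                    occupancy = ifelse(tot > 0, occ / tot, 0),
                    n_pixels = tot)
  attr(out, "center") <- center
  attr(out, "bin_width") <- bin_width
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Fit the travelling-wave form to a radial profile
#'
#' Fits the logistic wave `C(r) = 1 / (1 + exp((r - w) / (2a)))` to the
#' radial occupancy profile by nonlinear least squares.  `w` is the
#' wave-front coefficient (pixels): the extent of the dense spheroid core,
#' the distance at which the fitted density crosses 1/2.  `a` is the
#' diffusion coefficient (density/distance), describing how shallow the
#' slope of the invasion front is; it is constrained positive.  These are
#' static descriptors of the configuration of cells, not literal
#' reaction-diffusion constants.
#'
#' @param profile A [radial_profile()] (or data frame with `bin_center` and
#'   `occupancy`).
#' @return An object of class `wave_fit` with elements `wave_front`,
#'   `diffusion`, `rss` and `converged`.  Non-convergence is flagged, not
#'   silent.
#' @examples
#' r <- seq(0.5, 40.5, by = 1)
#' prof <- data.frame(bin_center = r, occupancy = 1 / (1 + exp((r - 10) / 4)))
#' fit_travelling_wave(prof)
#' @export
fit_travelling_wave <- function(profile) {
  r <- profile$bin_center
  y <- profile$occupancy
  if (length(r) < 4) stop("need at least 4 radial bins to fit the wave")
  if (max(y) - min(y) < 1e-12) stop("occupancy profile is constant; wave fit undefined")
  w0 <- half_crossing(r, y)
  rss_fun <- function(par) {
    pred <- 1 / (1 + exp((r - par[1]) / (2 * exp(par[2]))))
    sum((y - pred)^2)
  }
  best <- NULL
  for (a0 in c(0.5, 2, 8)) {   # few starts: the surface can be shallow in a
    o <- stats::optim(c(w0, log(a0)), rss_fun, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  structure(list(wave_front = best$par[1],
                 diffusion = exp(best$par[2]),
                 rss = best$value,
                 converged = best$convergence == 0),
            class = "wave_fit")
}

half_crossing <- function(r, y) {
  below <- which(y < 0.5)
  if (length(below) == 0) return(max(r))
  i <- below[1]
  if (i == 1) return(r[1])
  # linear interpolation between the bracketing bins
  r[i - 1] + (0.5 - y[i - 1]) * (r[i] - r[i - 1]) / (y[i] - y[i - 1])
}

#' @export
print.wave_fit <- function(x, ...) {
  cat(sprintf("wave fit: front w = %.3f px, diffusion a = %.3f (rss %.3g%s)\n",
              x$wave_front, x$diffusion, x$rss,
              if (!x$converged) ", NOT CONVERGED" else ""))
  invisible(x)
}

#' Invaded area of a mask
#'
#' Area of the convex hull of the occupied pixel centres, in pixels^2 — the
#' "area invaded" summary.  Fewer than 3 non-collinear pixels give area 0.
#'
#' @param mask 0/1 matrix.
#' @return Numeric area in pixels^2.
#' @examples
#' m <- matrix(0L, 12, 12); m[cbind(c(1, 11, 1), c(1, 1, 11))] <- 1L
#' invaded_area(m)  # right triangle with legs 10: area 50
#' @export
invaded_area <- function(mask) {
  mask <- as_binary_mask(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) < 3) return(0)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  if (length(h) < 3) return(0)
  polygon_area(idx[h, 1], idx[h, 2])
}

# shoelace formula; vertices in hull order
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Cell density of the invaded area
#'
#' Cells per pixel^2: a cell count divided by the invaded area.  The count
#' may be the number of set mask pixels (the 2D proxy, default when a mask
#' is given) or the true 3D cell count from a simulation snapshot, which is
#' never smaller since the z-collapse merges columns of cells.
#'
#' @param count_or_mask A cell count, or a 0/1 mask whose set pixels are
#'   counted.
#' @param area Invaded area in pixels^2; must be positive.
#' @return Density in cells per pixel^2.
#' @export
cell_density <- function(count_or_mask, area) {
  stopifnot(is.numeric(area), length(area) == 1L)
  if (area <= 0) stop("`area` must be positive")
  count <- if (is.matrix(count_or_mask)) sum(as_binary_mask(count_or_mask))
           else as.numeric(count_or_mask)
  stopifnot(count >= 0)
  count / area
}

#' Invasion summary of one mask
#'
#' Bundles the four invasion summary statistics for a single per-clone mask:
#' wave-front and diffusion coefficients from the travelling-wave fit,
#' convex-hull invaded area, and cell density.
#'
#' @inheritParams radial_profile
#' @param time Imaging day the mask belongs to.
#' @param clone Clone label.
#' @param count Optional true cell count (e.g. from a 3D snapshot); set
#'   pixels are used when omitted.
#' @return One-row data frame with columns `clone`, `time`, `wave_front`,
#'   `diffusion`, `area`, `density`.
#' @export
mask_summary <- function(mask, time = NA_real_, clone = NA_character_,
                         center = NULL, bin_width = 1, count = NULL) {
  mask <- as_binary_mask(mask)
  prof <- radial_profile(mask, center = center, bin_width = bin_width)
  fit <- fit_travelling_wave(prof)
  area <- invaded_area(mask)
  n <- if (is.null(count)) sum(mask) else count
  dens <- if (area > 0) n / area else 0
  data.frame(clone = clone, time = time,
             wave_front = fit$wave_front, diffusion = fit$diffusion,
             area = area, density = dens)
}

#' Summarize a simulated snapshot stack
#'
#' Applies [mask_summary()] to every snapshot and clone with at least one
#' occupied pixel, using the lattice centre and (optionally) the true 3D
#' cell counts.
#'
#' @param snaps A `ca_snapshots` object from [run_simulation()].
#' @param clones Which clones to summarize (default those present).
#' @param use_3d_counts Use the snapshot's 3D cell count for density rather
#'   than the number of set mask pixels.
#' @param bin_width Annulus width for the radial profile.
#' @return Data frame of invasion summaries, one row per snapshot x clone.
#' @export
summarize_snapshots <- function(snaps, clones = c("A", "B"),
                                use_3d_counts = FALSE, bin_width = 1) {
  rows <- list()
  for (s in snaps) {
    for (cl in clones) {
      m <- s$masks[[cl]]
      if (sum(m) == 0) next
      cnt <- if (use_3d_counts) s$counts[[cl]] else NULL
      rows[[length(rows) + 1L]] <-
        mask_summary(m, time = s$time, clone = cl, bin_width = bin_width,
                     count = cnt)
    }
  }
  do.call(rbind, rows)
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  stopifnot(is.matrix(mask), is.numeric(mask))
  if (!all(mask %in% c(0, 1)))
    stop("mask must be strictly binary (0/1)")
  storage.mode(mask) <- "integer"
  mask
}
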