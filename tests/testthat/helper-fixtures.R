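# Shared fixtures and independent oracles used across test files.

# build a lattice_state with cells at the given (x, y, z) rows
state_from_sites <- function(L, sites, clones = 1L) {
  occ <- array(0L, dim = c(L, L, L))
  sites <- matrix(sites, ncol = 3)
  occ[sites] <- as.integer(clones)
  spheroidABC:::new_lattice_state(occ)
}

# independent convex hull (Jarvis march / gift wrapping) + shoelace area,
# used as a second implementation to cross-check invaded_area()
jarvis_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cr <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
            (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("hull did not close")
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  m <- length(hx); j <- c(m, seq_len(m - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# simple binary dilation by the 8-neighbourhood
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  idx <- which(mask == 1, arr.ind = TRUE)
  for (dx in -1:1) for (dy in -1:1) {
    sh <- cbind(idx[, 1] + dx, idx[, 2] + dy)
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2]
    out[sh[ok, , drop = FALSE]] <- 1L
  }
  out
}

# small analytic databank for ABC/GA tests: one informative summary and one
# pure-noise summary, no simulator involved
toy_databank <- function(n = 400, seed = 42, noise_sd = 0.05) {
  prior <- prior_spec(theta = c(0, 1))
  forward <- function(theta, fseed) {
    set.seed(fseed)
    c(signal = theta$theta + stats::rnorm(1, 0, noise_sd),
      noise = stats::runif(1))
  }
  build_databank(prior, forward, n, seed)
}

# reduced-scale shared mono-culture databank, built once per test run
.shared <- new.env(parent = emptyenv())

shared_mono_prior <- function() prior_spec(proliferation = c(0.1, 1.5),
                                           motility = c(0, 10))

shared_mono_databank <- function() {
  if (is.null(.shared$mono_db)) {
    .shared$mono_db <- build_mono_databank(
      prior = shared_mono_prior(), days = 1:2, n = 400, seed = 20260917,
      lattice_edge = 40, seed_radius = 5)
  }
  .shared$mono_db
}

# observed mono-culture summary vector simulated at known rates
observed_mono <- function(p, m, seed, lattice_edge = 40, days = 1:2,
                          fnr = 0, fpr = 0) {
  cfg <- simulation_config(lattice_edge = lattice_edge, seed_radius = 5,
                           seeding_ratio = 1, end_time = max(days),
                           snapshot_interval = 1, rng_seed = seed)
  snaps <- suppressWarnings(run_simulation(cfg, phenotype_params(p, m)))
  rows <- lapply(snaps, function(s) {
    if (!s$time %in% days) return(NULL)
    mk <- s$masks$A
    if (fnr > 0 || fpr > 0)
      mk <- apply_segmentation_noise(mk, fnr, fpr, seed = seed + s$time)
    spheroidABC:::mask_summary_safe(mk, s$time, "A")
  })
  summary_vector(do.call(rbind, rows), days)
}

# synthetic mono-culture "results" with stated uncertainty, used when the
# interaction stage is exercised on its own
stated_mono_result <- function(p, m, p_sd = 0.08, m_sd = 0.5,
                               prior = shared_mono_prior()) {
  fit <- function(mean, sd, b) structure(
    list(mean = mean, sd = sd, lower = b[1], upper = b[2], loglik = NA_real_),
    class = "truncnorm_fit")
  structure(list(
    posterior = NULL,
    fits = list(proliferation = fit(p, p_sd, prior$proliferation),
                motility = fit(m, m_sd, prior$motility)),
    reports = NULL, observed = NULL), class = "monoculture_result")
}

# observed AUC for a synthetic co-culture experiment at known interaction I
# (received by clone A from clone B); returns the focal normalized-curve AUC
observed_auc_at <- function(I, seed, ratios = c(0.25, 0.5, 0.75), day = 2,
                            p = c(0.5, 0.5), m = c(2, 4),
                            lattice_edge = 40, mono_reps = 2) {
  Im <- matrix(c(0, I, 0, 0), 2, 2, byrow = TRUE)
  params <- list(phenotype_params(p[1], m[1]), phenotype_params(p[2], m[2]))
  sim_area <- function(ratio, s) {
    cfg <- simulation_config(lattice_edge = lattice_edge, seed_radius = 5,
                             seeding_ratio = ratio, end_time = day,
                             snapshot_interval = day, rng_seed = s)
    snaps <- suppressWarnings(run_simulation(cfg, params,
                                             interaction_model(Im)))
    invaded_area(snaps[[length(snaps)]]$masks$A)
  }
  mono <- data.frame(area = vapply(seq_len(mono_reps), function(i)
    sim_area(1, seed * 1000 + i), numeric(1)), time = day)
  co <- data.frame(ratio = ratios,
                   area = vapply(seq_along(ratios), function(i)
                     sim_area(ratios[i], seed * 1000 + 100 + i), numeric(1)),
                   time = day)
  auc_of_curve(normalized_ratio_curve(co, mono, "A"))
}

# reduced-scale shared interaction databank (focal clone A), built once
shared_interaction_databank <- function() {
  if (is.null(.shared$int_db)) {
    monoA <- stated_mono_result(0.5, 2)
    monoB <- stated_mono_result(0.5, 4)
    .shared$int_db <- build_interaction_databank(
      monoA, monoB, focal = "A", prior = prior_spec(interaction = c(-15, 15)),
      ratios = c(0.25, 0.5, 0.75), day = 2, n = 150, seed = 715,
      lattice_edge = 40, seed_radius = 5)
  }
  .shared$int_db
}
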