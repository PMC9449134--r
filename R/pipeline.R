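#' Per-day invasion summary vector for ABC
#'
#' Flattens invasion summaries at the requested days into the named vector
#' compared inside ABC: `wave_front_d<t>`, `diffusion_d<t>`, `area_d<t>`,
#' `density_d<t>` for each day `t`.  Day 0 carries no information (every
#' culture starts from the same seeded ball, whose constant-occupancy
#' profile has no wave front) and is excluded by convention.
#'
#' @param summaries Data frame from [summarize_snapshots()] /
#'   [mask_summary()] for one clone (replicates allowed; averaged per day).
#' @param days Days to include.
#' @return Named numeric vector, 4 entries per day.
#' @export
summary_vector <- function(summaries, days) {
  stats <- c("wave_front", "diffusion", "area", "density")
  out <- numeric(0)
  for (d in days) {
    sub <- summaries[summaries$time == d, , drop = FALSE]
    v <- if (nrow(sub) == 0) c(0, 0, 0, 0)   # clone extinct by this day
         else vapply(stats, function(s) mean(sub[[s]]), numeric(1))
    names(v) <- sprintf("%s_d%g", stats, d)
    out <- c(out, v)
  }
  out
}

# wave fit that degrades gracefully on (near-)constant profiles, for use
# deep inside forward models where an error would abort a whole databank
wave_fit_or_default <- function(prof) {
  tryCatch(fit_travelling_wave(prof),
           error = function(e) list(wave_front = max(prof$bin_center),
                                    diffusion = attr(prof, "bin_width") / 4,
                                    rss = NA_real_, converged = FALSE))
}

mask_summary_safe <- function(mask, time, clone, bin_width = 1) {
  if (sum(mask) == 0)
    return(data.frame(clone = clone, time = time, wave_front = 0,
                      diffusion = 0, area = 0, density = 0))
  prof <- radial_profile(mask, bin_width = bin_width)
  fit <- wave_fit_or_default(prof)
  area <- invaded_area(mask)
  data.frame(clone = clone, time = time,
             wave_front = fit$wave_front, diffusion = fit$diffusion,
             area = area, density = if (area > 0) sum(mask) / area else 0)
}

snapshot_summaries <- function(snaps, clone, days, bin_width = 1) {
  do.call(rbind, lapply(snaps, function(s) {
    if (!s$time %in% days) return(NULL)
    mask_summary_safe(s$masks[[clone]], s$time, clone, bin_width)
  }))
}

#' Build a mono-culture simulation databank
#'
#' Draws (proliferation, motility) pairs from the uniform prior, runs one
#' seeded mono-culture simulation per draw and records the per-day invasion
#' summary vector — the substrate for mono-culture ABC.
#'
#' @param prior [prior_spec()] with `proliferation` and `motility` bounds.
#' @param days Days whose summaries enter the comparison (excluding 0).
#' @param n Databank size.
#' @param seed Master seed.
#' @param lattice_edge,seed_radius Simulator geometry.
#' @param aggression Push distance used in the simulations.
#' @param bin_width Radial profile bin width.
#' @return An `abc_databank` (see [build_databank()]).
#' @export
build_mono_databank <- function(prior = default_phenotype_prior(), days = 1:3,
                                n = 2000, seed = 1L, lattice_edge = 120L,
                                seed_radius = 5, aggression = 1L,
                                bin_width = 1) {
  days <- days[days > 0]
  forward <- function(theta, fseed) {
    cfg <- simulation_config(lattice_edge = lattice_edge,
                             seed_radius = seed_radius, seeding_ratio = 1,
                             end_time = max(days), snapshot_interval = 1,
                             rng_seed = fseed)
    ph <- phenotype_params(theta$proliferation, theta$motility, aggression)
    snaps <- suppressWarnings(run_simulation(cfg, ph))
    summary_vector(snapshot_summaries(snaps, "A", days, bin_width), days)
  }
  build_databank(prior, forward, n, seed)
}

#' Infer mono-culture phenotype rates by rejection ABC
#'
#' Compares an observed per-day summary vector (from [summary_vector()])
#' against a mono-culture databank, accepts the closest parameter draws and
#' fits truncated normal distributions (bounded by the prior) to the
#' accepted proliferation and motility samples.  The fitted distributions
#' propagate the phenotype uncertainty into co-culture inference.
#'
#' @param observed Named numeric summary vector covering the databank's
#'   summary names.
#' @param databank From [build_mono_databank()].
#' @param weights Summary weights (see [ga_optimize_weights()]); equal by
#'   default.
#' @param level HDI level for reporting.
#' @param bin_width Modal-interval bin width for rates.
#' @param abc_opts Options forwarded to [abc_reject()].
#' @return A `monoculture_result`: list with `posterior` (accepted draws),
#'   `fits` (per-parameter `truncnorm_fit`), `reports` (HDI and modal
#'   interval per parameter) and `observed`.
#' @export
infer_monoculture <- function(observed, databank, weights = NULL,
                              level = 0.95, bin_width = 0.5,
                              abc_opts = list()) {
  post <- do.call(abc_reject, c(list(databank = databank, obs = observed,
                                     weights = weights), abc_opts))
  prior <- attr(databank, "prior")
  pn <- attr(databank, "par_names")
  fits <- reports <- stats::setNames(vector("list", length(pn)), pn)
  for (p in pn) {
    fits[[p]] <- fit_truncated_normal(post[[p]], prior[[p]])
    reports[[p]] <- credible_report(post[[p]], level, bin_width)
  }
  structure(list(posterior = post, fits = fits, reports = reports,
                 observed = observed),
            class = "monoculture_result")
}

#' @export
print.monoculture_result <- function(x, ...) {
  cat("mono-culture ABC result\n")
  for (p in names(x$fits)) {
    h <- x$reports[[p]]$hdi
    cat(sprintf("  %s: mean %.3g, sd %.3g, 95%% HDI (%.3g, %.3g)\n",
                p, x$fits[[p]]$mean, x$fits[[p]]$sd, h[1], h[2]))
  }
  invisible(x)
}

focal_seeding_ratio <- function(focal, ratio_focal) {
  if (clone_index(focal) == 1L) ratio_focal else 1 - ratio_focal
}

#' Build a co-culture interaction databank
#'
#' The second-stage substrate: each row draws the two clones' proliferation
#' and motility rates from the truncated-normal mono-culture fits
#' (propagating first-stage uncertainty), draws the interaction strength
#' received by the focal clone from its uniform prior, simulates the focal
#' mono-culture plus a co-culture at every seeding ratio, and records the
#' AUC of the mono-culture-normalized area curve at the analysis day.
#' Interactions are inferred one clone at a time: the strength received by
#' the non-focal clone is fixed at zero.
#'
#' @param mono_focal,mono_other `monoculture_result`s for the focal and the
#'   other clone.
#' @param focal `"A"` or `"B"`: the clone receiving the interaction.
#' @param prior [prior_spec()] with an `interaction` entry.
#' @param ratios Focal-clone seeding fractions of the co-cultures.
#' @param day Analysis day for the AUC (the last common imaging day by
#'   convention).
#' @param n Databank size.
#' @param seed Master seed.
#' @param lattice_edge,seed_radius,aggression Simulator settings.
#' @return An `abc_databank` with parameter `interaction` and summary
#'   `auc`.
#' @export
build_interaction_databank <- function(mono_focal, mono_other, focal = "A",
                                       prior = default_interaction_prior(),
                                       ratios = c(0.75, 0.5), day = 3,
                                       n = 2000, seed = 1L,
                                       lattice_edge = 120L, seed_radius = 5,
                                       aggression = 1L) {
  fi <- clone_index(focal)
  forward <- function(theta, fseed) {
    set.seed(fseed)
    pf <- phenotype_params(rtruncnorm_fit(1, mono_focal$fits$proliferation),
                           rtruncnorm_fit(1, mono_focal$fits$motility),
                           aggression)
    po <- phenotype_params(rtruncnorm_fit(1, mono_other$fits$proliferation),
                           rtruncnorm_fit(1, mono_other$fits$motility),
                           aggression)
    I <- matrix(0, 2, 2)
    I[fi, 3 - fi] <- theta$interaction
    model <- interaction_model(I)
    params <- if (fi == 1L) list(pf, po) else list(po, pf)
    sim_seeds <- derive_seeds(fseed, length(ratios) + 1)
    run_one <- function(ratio_focal, s) {
      cfg <- simulation_config(lattice_edge = lattice_edge,
                               seed_radius = seed_radius,
                               seeding_ratio = focal_seeding_ratio(focal, ratio_focal),
                               end_time = day, snapshot_interval = day,
                               rng_seed = s)
      snaps <- suppressWarnings(run_simulation(cfg, params, model))
      last <- snaps[[length(snaps)]]
      mask_summary_safe(last$masks[[c("A", "B")[fi]]], day, focal)
    }
    mono <- run_one(1, sim_seeds[1])
    if (mono$area <= 0) return(c(auc = 0))  # focal failed to invade at all
    co <- do.call(rbind, Map(function(r, s) {
      x <- run_one(r, s); x$ratio <- r; x
    }, ratios, sim_seeds[-1]))
    curve <- normalized_ratio_curve(co, mono, focal)
    c(auc = auc_of_curve(curve))
  }
  build_databank(prior, forward, n, seed)
}

#' Observed AUC of a clone's normalized ratio curve
#'
#' From a manifest with loaded masks (see [read_masks()]), computes the
#' focal clone's invaded area in every co-culture well at the analysis day,
#' normalizes by the mean same-day mono-culture area, fits the quadratic
#' and returns its AUC.
#'
#' @param masks_manifest Manifest data frame with a `mask` list-column.
#' @param focal Focal clone label (`"A"` or `"B"`).
#' @param day Analysis day.
#' @return The observed AUC (scalar), with the `ratio_curve` in attribute
#'   `curve`.
#' @export
observed_interaction_auc <- function(masks_manifest, focal = "A", day = 3) {
  m <- masks_manifest
  stopifnot("mask" %in% names(m))
  cl <- c("A", "B")[clone_index(focal)]
  sub <- m[m$day == day & m$clone == cl, , drop = FALSE]
  if (nrow(sub) == 0) stop("no masks for clone ", cl, " at day ", day)
  is_mono <- sub$condition == paste0("mono_", cl)
  is_co <- grepl("^co", sub$condition)
  if (!any(is_mono)) stop("missing mono-culture reference for clone ", cl)
  if (length(unique(sub$ratio[is_co])) < 2)
    stop("need co-cultures at >= 2 distinct seeding ratios")
  area_of <- function(rows) vapply(rows$mask, invaded_area, numeric(1))
  mono <- data.frame(area = area_of(sub[is_mono, ]), time = day)
  co <- sub[is_co, , drop = FALSE]
  co_df <- data.frame(
    ratio = vapply(co$ratio, function(r) {
      if (clone_index(focal) == 1L) r else 1 - r
    }, numeric(1)),
    area = area_of(co), time = day)
  curve <- normalized_ratio_curve(co_df, mono, focal)
  structure(auc_of_curve(curve), curve = curve)
}

#' Infer the interaction strength received by a clone
#'
#' Rejection ABC with the AUC of the normalized area-vs-ratio curve as the
#' (single) summary statistic, against a co-culture databank built by
#' [build_interaction_databank()].  Reports the accepted interaction
#' samples, their HDI and modal interval.
#'
#' @param observed_auc Observed AUC (from [observed_interaction_auc()] or a
#'   scalar).
#' @param databank Interaction databank.
#' @param level HDI level.
#' @param bin_width Modal-interval bin width (1.0 for interaction
#'   strengths).
#' @param abc_opts Options forwarded to [abc_reject()].
#' @return An `interaction_posterior`: list with `samples`, `hdi`,
#'   `modal_interval`, `observed_auc` and `sign` (`"positive"`,
#'   `"negative"` or `"neutral"` according to whether the HDI excludes 0).
#' @export
infer_interaction <- function(observed_auc, databank, level = 0.95,
                              bin_width = 1.0, abc_opts = list()) {
  post <- do.call(abc_reject,
                  c(list(databank = databank,
                         obs = c(auc = as.numeric(observed_auc))),
                    abc_opts))
  s <- post$interaction
  h <- hdi(s, level)
  structure(list(samples = s, hdi = h,
                 modal_interval = modal_interval(s, bin_width),
                 observed_auc = as.numeric(observed_auc),
                 sign = hdi_sign(h), level = level),
            class = "interaction_posterior")
}

hdi_sign <- function(h) {
  if (h[1] > 0) "positive" else if (h[2] < 0) "negative" else "neutral"
}

#' @export
print.interaction_posterior <- function(x, ...) {
  cat(sprintf(
    "interaction posterior: %s; 95%% HDI (%.2f, %.2f), modal interval (%.2f, %.2f)\n",
    x$sign, x$hdi[1], x$hdi[2], x$modal_interval[1], x$modal_interval[2]))
  invisible(x)
}

#' Maximal effect of an interaction on motility
#'
#' Pairs draws of the base motility rate `m` (from the mono-culture
#' truncated-normal fit) with accepted interaction strengths `I` and forms
#' `max(0, m + I)` — the effective motility at the upper bound where the
#' other clone's proportion is 1.  Comparing the two distributions shows
#' the largest shift the interaction could produce.
#'
#' @param motility_fit `truncnorm_fit` of the clone's motility.
#' @param interaction_posterior An `interaction_posterior`.
#' @param n Number of paired draws.
#' @return Data frame with columns `motility` and `with_interaction`;
#'   attribute `shift` is the fraction of `m + I` draws exceeding the
#'   median base motility.
#' @export
maximal_effect <- function(motility_fit, interaction_posterior, n = 4000) {
  m <- rtruncnorm_fit(n, motility_fit)
  I <- sample(interaction_posterior$samples, n, replace = TRUE)
  out <- data.frame(motility = m, with_interaction = pmax(0, m + I))
  attr(out, "shift") <- mean(out$with_interaction > stats::median(m))
  out
}

#' Classify the interaction between two clones
#'
#' Combines the per-clone sign calls (positive / negative / neutral, by
#' whether the 95% HDI of the received interaction excludes zero) into the
#' ecological pair label: mutualism (+,+), commensalism (+,0), exploitation
#' (+,-), competition (-,-), amensalism (-,0) and neutral (0,0).  The label
#' is a pure function of the two sign calls.
#'
#' @param post_A,post_B `interaction_posterior`s (or HDI vectors) for the
#'   interaction received by clone A and clone B.
#' @return List with `sign_A`, `sign_B` and `label`.
#' @export
classify_interaction <- function(post_A, post_B) {
  sgn <- function(p) {
    if (inherits(p, "interaction_posterior")) p$sign
    else hdi_sign(as.numeric(p))
  }
  a <- sgn(post_A); b <- sgn(post_B)
  label <- switch(
    paste(a, b),
    "positive positive" = "mutualism",
    "positive neutral" = , "neutral positive" = "commensalism",
    "positive negative" = , "negative positive" = "exploitation",
    "negative negative" = "competition",
    "negative neutral" = , "neutral negative" = "amensalism",
    "neutral neutral" = "neutral")
  list(sign_A = a, sign_B = b, label = label)
}
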