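#' Specify a synthetic co-evolution experiment
#'
#' Describes a fully synthetic version of the invasion assay with known
#' ground truth: mono-cultures of each clone plus co-cultures at the given
#' seeding ratios, imaged at 24 h intervals, each mask being the 2D
#' collapse of a 3D simulation with optional segmentation-like noise.  The
#' defaults mirror the assay design: ratios 75:25 and 50:50, four daily
#' imaging points, and (for robustness studies only) small false-negative /
#' false-positive pixel rates; set the noise rates to zero for clean masks.
#'
#' @param params_A,params_B [phenotype_params()] of the two clones.
#' @param model [interaction_model()] giving the true interaction strengths.
#' @param ratios Seeding fractions of clone A used in co-cultures.
#' @param days Imaging days (24 h intervals).
#' @param replicates Replicates per condition.
#' @param fnr,fpr Segmentation false-negative / false-positive pixel rates.
#' @param master_seed Integer master seed; fully determines the dataset.
#' @param lattice_edge,seed_radius Simulator geometry.
#' @return An object of class `synthetic_ground_truth`.
#' @export
synthetic_ground_truth <- function(params_A, params_B,
                                   model = interaction_model(),
                                   ratios = c(0.75, 0.5),
                                   days = 0:3, replicates = 3,
                                   fnr = 0, fpr = 0,
                                   master_seed = 1L,
                                   lattice_edge = 120L, seed_radius = 5) {
  stopifnot(inherits(params_A, "phenotype_params"),
            inherits(params_B, "phenotype_params"),
            all(ratios > 0 & ratios < 1), length(days) >= 1,
            replicates >= 1, fnr >= 0, fnr < 1, fpr >= 0, fpr < 1)
  structure(list(params_A = params_A, params_B = params_B, model = model,
                 ratios = ratios, days = sort(unique(days)),
                 replicates = as.integer(replicates),
                 fnr = fnr, fpr = fpr,
                 master_seed = as.integer(master_seed),
                 lattice_edge = as.integer(lattice_edge),
                 seed_radius = seed_radius),
            class = "synthetic_ground_truth")
}

# stable seed per (condition, replicate, purpose) derived from the master
# seed; plain 31-polynomial string hash kept below 2^31
condition_seed <- function(master, condition, replicate, salt = 0) {
  m <- 2^31 - 1
  h <- 0
  for (b in utf8ToInt(condition)) h <- (h * 31 + b) %% m
  s <- (h + master * 1000003 + replicate * 7919 + salt * 104729) %% (m - 1)
  as.integer(s + 1)
}

#' Generate a synthetic experiment with known ground truth
#'
#' Runs the simulator for every condition (mono-culture of each clone and a
#' co-culture per seeding ratio) and replicate, collapses the state to
#' per-clone masks at each imaging day, optionally corrupts them with
#' segmentation-like noise, and writes the mask files, a manifest CSV and a
#' ground-truth JSON.  Per-condition RNG seeds are derived from the master
#' seed by stable hashing, so identical specifications yield byte-identical
#' datasets.
#'
#' @param truth A [synthetic_ground_truth()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly; files are written under
#'   `out_dir` (`manifest.csv`, `ground_truth.json`, one `.pbm` per
#'   well/day/clone).
#' @export
generate_synthetic_experiment <- function(truth, out_dir) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conditions <- c("mono_A", "mono_B", paste0("co_", truth$ratios))
  cond_ratio <- c(1, 0, truth$ratios)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    ratio <- cond_ratio[ci]
    clones <- if (cond == "mono_A") "A" else if (cond == "mono_B") "B"
              else c("A", "B")
    for (rep in seq_len(truth$replicates)) {
      seed <- condition_seed(truth$master_seed, cond, rep)
      cfg <- simulation_config(lattice_edge = truth$lattice_edge,
                               seed_radius = truth$seed_radius,
                               seeding_ratio = ratio,
                               end_time = max(truth$days),
                               snapshot_interval = 1,
                               rng_seed = seed)
      snaps <- run_simulation(cfg, list(truth$params_A, truth$params_B),
                              truth$model)
      well <- paste0(cond, "_r", rep)
      for (s in snaps) {
        if (!s$time %in% truth$days) next
        for (cl in clones) {
          m <- s$masks[[cl]]
          if (truth$fnr > 0 || truth$fpr > 0)
            m <- apply_segmentation_noise(
              m, truth$fnr, truth$fpr,
              seed = condition_seed(truth$master_seed, cond, rep,
                                    salt = s$time * 2 + (cl == "B")))
          fn <- sprintf("%s_%s_%d.pbm", well, cl, s$time)
          write_mask(m, file.path(out_dir, fn))
          rows[[length(rows) + 1L]] <- data.frame(
            path = fn, well = well, day = s$time, clone = cl,
            ratio = ratio, replicate = rep, condition = cond)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  gt <- list(params_A = unclass(truth$params_A),
             params_B = unclass(truth$params_B),
             interaction = truth$model$strengths,
             neighborhood = truth$model$neighborhood,
             ratios = truth$ratios, days = truth$days,
             replicates = truth$replicates,
             fnr = truth$fnr, fpr = truth$fpr,
             master_seed = truth$master_seed,
             lattice_edge = truth$lattice_edge,
             seed_radius = truth$seed_radius)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Corrupt a mask with segmentation-like noise
#'
#' Emulates imperfect image segmentation: each occupied pixel is dropped
#' (false negative) with probability `fnr`, and each empty pixel lying
#' inside the convex hull of the original mask is set (false positive) with
#' probability `fpr`.  False positives are confined to the hull because
#' segmentation errors occur around the spheroid, not in empty matrix.
#'
#' @param mask 0/1 matrix.
#' @param fnr,fpr Error rates in `[0, 1)`.
#' @param seed Optional integer seed for reproducible noise.
#' @return The corrupted 0/1 matrix.
#' @export
apply_segmentation_noise <- function(mask, fnr, fpr, seed = NULL) {
  mask <- as_binary_mask(mask)
  stopifnot(fnr >= 0, fnr < 1, fpr >= 0, fpr < 1)
  if (!is.null(seed)) set.seed(seed)
  out <- mask
  occ <- which(mask == 1)
  if (fnr > 0 && length(occ) > 0)
    out[occ[stats::runif(length(occ)) < fnr]] <- 0L
  if (fpr > 0 && length(occ) >= 3) {
    idx <- which(mask == 1, arr.ind = TRUE)
    h <- grDevices::chull(idx[, 1], idx[, 2])
    if (length(h) >= 3) {
      emp <- which(mask == 0, arr.ind = TRUE)
      inside <- in_convex_polygon(emp[, 1], emp[, 2], idx[h, 1], idx[h, 2])
      cand <- emp[inside, , drop = FALSE]
      if (nrow(cand) > 0)
        out[cand[stats::runif(nrow(cand)) < fpr, , drop = FALSE]] <- 1L
    }
  }
  out
}

# point-in-convex-polygon: all cross products with the (ordered) hull edges
# share a sign (boundary counts as inside)
in_convex_polygon <- function(px, py, hx, hy) {
  n <- length(hx)
  pos <- rep(TRUE, length(px)); neg <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    pos <- pos & cr >= 0
    neg <- neg & cr <= 0
  }
  pos | neg
}
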