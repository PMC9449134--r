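#' Read and write binary masks
#'
#' Masks are stored as portable bitmaps (plain-text PBM, magic `P1`), a
#' standard image format readable by ImageJ, scikit-image and netpbm tools.
#' `read_mask()` also accepts plain-text PGM (`P2`) files but insists that
#' every pixel is strictly binary (0 or the maximum gray value); anything
#' else is rejected with an error naming the file, since a segmentation
#' mask must not contain intermediate values.
#'
#' @param mask 0/1 integer matrix (rows = x, columns = y).
#' @param path File path (conventionally `{well}_{clone}_{day}.pbm`).
#' @return `read_mask()` returns a 0/1 integer matrix; `write_mask()`
#'   returns `path` invisibly.  Round-trips are lossless.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(mask), nrow(mask))), con)
  utils::write.table(mask, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)                      # strip comments
  tok <- scan(text = txt, what = character(), quiet = TRUE)
  if (length(tok) < 3) stop("malformed mask file: ", path)
  magic <- tok[1]
  if (!magic %in% c("P1", "P2"))
    stop("unsupported mask format (expect plain PBM/PGM): ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  if (magic == "P1") {
    vals <- as.integer(tok[-(1:3)])
  } else {
    maxval <- as.integer(tok[4])
    vals <- as.integer(tok[-(1:4)])
    if (!all(vals %in% c(0L, maxval)))
      stop("non-binary pixel values in mask file: ", path)
    vals <- as.integer(vals == maxval)
  }
  if (length(vals) != w * h) stop("pixel count mismatch in mask file: ", path)
  if (!all(vals %in% c(0L, 1L)))
    stop("non-binary pixel values in mask file: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Experiment manifests
#'
#' A manifest is the experiment's table of contents: one row per mask file
#' with columns `path`, `well`, `day`, `clone`, `ratio` (seeding fraction of
#' clone A), `replicate` and `condition`.  `(well, day, clone)` must be
#' unique and ratios must lie in `[0, 1]`.
#'
#' @param manifest Data frame with the columns above.
#' @param path CSV file path.
#' @return `read_manifest()` returns the validated data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  need <- c("path", "well", "day", "clone", "ratio", "replicate", "condition")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m[, c("well", "day", "clone")]))
    stop("(well, day, clone) combinations must be unique in a manifest")
  if (any(m$ratio < 0 | m$ratio > 1))
    stop("manifest ratios must lie in [0, 1]")
  invisible(m)
}

#' Load all masks referenced by a manifest
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param base_dir Directory that relative mask paths are resolved against.
#' @return The manifest with a list-column `mask` holding the arrays.
#' @export
read_masks <- function(manifest, base_dir = ".") {
  validate_manifest(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$path), manifest$path,
                  file.path(base_dir, manifest$path))
  manifest$mask <- lapply(paths, read_mask)
  manifest
}
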