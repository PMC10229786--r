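# Reading/writing cohort manifests, ROI time-series files and atlas geometry;
# the canonical in-memory cohort is a tibble with a list-column of t x m
# signal matrices (rows = time points, columns = ROIs in atlas order).

#' Compute the pairwise Euclidean distance matrix of ROI centroids
#'
#' @param coords Numeric matrix of ROI centroids, one row per ROI, columns
#'   x/y/z in mm (any column count >= 1 is accepted).
#' @return A list with `dist` (symmetric m x m matrix of Euclidean distances,
#'   zero diagonal) and `max_dist` (the largest off-diagonal distance, the
#'   `D` used by the spatial-augmentation radius `r * D`).
#' @examples
#' compute_distance_matrix(rbind(c(0, 0, 0), c(3, 4, 0)))
#' @export
compute_distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) {
    abort("`coords` must contain at least 2 ROI centroids.")
  }
  if (!all(is.finite(coords))) {
    abort("`coords` contains non-finite values.")
  }
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  list(dist = d, max_dist = max(d))
}

#' Construct an atlas geometry object
#'
#' Bundles ROI names, centroid coordinates and the pairwise Euclidean
#' distance matrix used by the spatial augmentation module.
#'
#' @param roi_names Character vector of m ROI names (must be unique).
#' @param coords Numeric m x 3 matrix of centroid coordinates (MNI mm).
#' @return An object of class `atlas_geometry`: a list with `roi` (a tibble
#'   with columns roi_name, x, y, z), `dist`, `max_dist` and `m`.
#' @export
atlas_geometry <- function(roi_names, coords) {
  coords <- as.matrix(coords)
  roi_names <- as.character(roi_names)
  if (length(roi_names) != nrow(coords)) {
    abort("`roi_names` length must equal the number of coordinate rows.")
  }
  if (anyDuplicated(roi_names)) {
    abort("ROI names must be unique.")
  }
  if (ncol(coords) != 3) {
    abort("`coords` must have 3 columns (x, y, z in mm).")
  }
  dm <- compute_distance_matrix(coords)
  structure(
    list(
      roi = tibble(
        roi_name = roi_names,
        x = coords[, 1], y = coords[, 2], z = coords[, 3]
      ),
      dist = dm$dist,
      max_dist = dm$max_dist,
      m = nrow(coords)
    ),
    class = "atlas_geometry"
  )
}

#' @export
print.atlas_geometry <- function(x, ...) {
  cat(sprintf(
    "<atlas_geometry> %d ROIs, max pairwise distance D = %.2f mm\n",
    x$m, x$max_dist
  ))
  print(head(x$roi, 5))
  if (x$m > 5) cat(sprintf("# ... with %d more ROIs\n", x$m - 5))
  invisible(x)
}

#' Read an atlas geometry table
#'
#' Accepts either a CSV with columns `roi_name,x,y,z` or a BrainNet-Viewer
#' `.node` layout (whitespace-delimited `x y z color size label`).
#'
#' @param path Path to the atlas file.
#' @return An [atlas_geometry()] object.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) abort(sprintf("Atlas file not found: %s", path))
  if (grepl("\\.node$", path, ignore.case = TRUE)) {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) {
      abort("BrainNet .node files need 6 columns: x y z color size label.")
    }
    return(atlas_geometry(df[[6]], as.matrix(df[, 1:3])))
  }
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("roi_name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort("Atlas CSV must have columns roi_name,x,y,z.")
  }
  atlas_geometry(df$roi_name, as.matrix(df[, c("x", "y", "z")]))
}

#' Write an atlas geometry table to CSV
#'
#' @param geometry An [atlas_geometry()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(geometry, path) {
  readr::write_csv(geometry$roi, path)
  invisible(path)
}

# Delimiter/header auto-detection: comma if the first line contains one,
# otherwise any whitespace; a header is assumed when the first line has
# non-numeric fields.
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- scan(
    text = first, what = "character",
    sep = if (sep == ",") "," else "", quiet = TRUE
  )
  has_header <- suppressWarnings(anyNA(as.numeric(fields)))
  read.table(path, header = has_header, sep = sep)
}

#' Read one subject's ROI time-series matrix
#'
#' Reads a delimited text file (tab-, comma- or whitespace-separated, with an
#' optional single header row) of shape t x m: rows are time points, columns
#' are ROIs in atlas order.
#'
#' @param path Path to the time-series file.
#' @return A numeric t x m matrix without dimnames.
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("Time-series file not found: %s", path))
  df <- read_delim_auto(path)
  x <- as.matrix(df)
  if (!is.numeric(x)) abort(sprintf("Non-numeric values in %s", path))
  if (anyNA(x)) abort(sprintf("Missing values in %s", path))
  dimnames(x) <- NULL
  x
}

#' Write one subject's ROI time-series matrix
#'
#' Writes tab-delimited text at full double precision so a write/read
#' round-trip reproduces the matrix exactly.
#'
#' @param signals Numeric t x m matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(signals, path) {
  df <- as.data.frame(signals)
  names(df) <- paste0("V", seq_len(ncol(df)))
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

# Per-column z-scoring (denominator: sample sd). Constant columns are an
# error because a zero-variance ROI has no defined correlation.
zscore_columns <- function(x, roi_names = NULL, context = "") {
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- which(sds == 0 | !is.finite(sds))[1]
    nm <- if (!is.null(roi_names)) roi_names[bad] else sprintf("column %d", bad)
    abort(sprintf("Constant ROI signal (%s)%s: z-scoring undefined.", nm, context))
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Assemble a cohort tibble from in-memory signal matrices
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param signals List of numeric t x m matrices, one per subject.
#' @param label Vector of class labels (coerced to factor).
#' @param normalize Z-score each ROI column? Default `TRUE`, matching the
#'   preprocessing convention that ROI signals are normalized before network
#'   construction.
#' @return A cohort tibble with columns `subject_id`, `label`, `signals`.
#' @export
new_cohort <- function(subject_id, signals, label, normalize = TRUE) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) abort("Subject ids must be unique.")
  if (length(signals) != length(subject_id)) {
    abort("`signals` must have one matrix per subject.")
  }
  signals <- purrr::map2(signals, subject_id, function(x, id) {
    x <- as.matrix(x)
    dimnames(x) <- NULL
    if (anyNA(x) || !is.numeric(x)) {
      abort(sprintf("Subject %s: signals must be numeric without NAs.", id))
    }
    if (nrow(x) < 2 || ncol(x) < 2) {
      abort(sprintf("Subject %s: need at least 2 time points and 2 ROIs.", id))
    }
    if (normalize) zscore_columns(x, context = sprintf(" for subject %s", id)) else x
  })
  tibble(
    subject_id = subject_id,
    label = factor(label),
    signals = signals
  )
}

#' Load a cohort manifest plus atlas geometry
#'
#' The manifest is a CSV with columns `subject_id,path,label`; relative paths
#' are resolved against the manifest's directory. Every subject file must be
#' a t x m delimited table with m equal to the atlas ROI count. Signals are
#' z-scored per ROI column at load time unless `normalize = FALSE`.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param atlas_path Path to the atlas geometry file (see [read_atlas()]).
#' @param normalize Z-score columns at load time (default `TRUE`).
#' @return A list with `cohort` (tibble: subject_id, label, signals) in
#'   manifest order and `geometry` (an [atlas_geometry()]).
#' @export
load_cohort <- function(manifest_path, atlas_path, normalize = TRUE) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("Manifest not found: %s", manifest_path))
  }
  geometry <- read_atlas(atlas_path)
  man <- read.table(manifest_path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man))) {
    abort("Manifest must have columns subject_id,path,label.")
  }
  base <- dirname(manifest_path)
  signals <- purrr::map2(man$path, man$subject_id, function(p, id) {
    full <- if (file.exists(p)) p else file.path(base, p)
    if (!file.exists(full)) {
      abort(sprintf("Subject %s: time-series file not found (%s).", id, p))
    }
    x <- read_time_series(full)
    if (ncol(x) != geometry$m) {
      abort(sprintf(
        "Subject %s: %d ROI columns but the atlas defines %d ROIs.",
        id, ncol(x), geometry$m
      ))
    }
    x
  })
  cohort <- new_cohort(man$subject_id, signals, man$label, normalize = normalize)
  list(cohort = cohort, geometry = geometry)
}

#' Write a cohort to per-subject files plus a manifest
#'
#' Inverse of [load_cohort()]: each subject's signal matrix is written as a
#' tab-delimited file `<subject_id>.tsv` under `dir`, and a manifest CSV is
#' written with any provenance columns (`source_id`, `augment`, `k`) present
#' in the cohort carried along.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if missing).
#' @param manifest_name File name for the manifest CSV.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest_name = "manifest.csv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".tsv"))
  purrr::walk2(cohort$signals, paths, write_time_series)
  man <- tibble(
    subject_id = cohort$subject_id,
    path = basename(paths),
    label = as.character(cohort$label)
  )
  for (col in c("source_id", "augment", "k")) {
    if (col %in% names(cohort)) man[[col]] <- cohort[[col]]
  }
  mp <- file.path(dir, manifest_name)
  readr::write_csv(man, mp)
  invisible(mp)
}
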