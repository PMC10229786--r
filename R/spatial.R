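# Spatial augmentation: each ROI's time series is replaced by the mean over
# its spatially constrained nearest-neighbour set. Varying the neighbour
# count k yields distinct augmented samples from one subject.

#' Build the constrained nearest-neighbour set of an ROI
#'
#' The neighbour set C_i of node i holds i itself plus up to `k` other nodes,
#' chosen nearest-first by Euclidean centroid distance, subject to the radius
#' restriction d(i, s) < r * D where D is the largest pairwise distance in
#' the atlas. A node strictly farther than the radius is never included, and
#' a nearer node is never excluded in favour of a farther one. Distance ties
#' are broken by ascending node index so the set is deterministic.
#'
#' @param i Node index (1-based).
#' @param geometry An [atlas_geometry()].
#' @param k Maximum number of neighbours beyond the node itself
#'   (`0 <= k <= m - 1`).
#' @param r Radius fraction in (0, 1); the admission radius is `r * D`.
#' @return Integer vector of member node indices, sorted ascending, always
#'   containing `i`.
#' @export
build_neighbor_set <- function(i, geometry, k, r = 0.5) {
  m <- geometry$m
  if (i < 1 || i > m) abort(sprintf("Node index %d out of range 1..%d.", i, m))
  if (r <= 0 || r >= 1) abort("`r` must lie strictly in (0, 1).")
  if (k < 0 || k > m - 1) abort(sprintf("`k` must lie in 0..%d.", m - 1))
  if (k == 0) return(i)
  d <- geometry$dist[i, ]
  cand <- setdiff(seq_len(m), i)
  cand <- cand[d[cand] < r * geometry$max_dist]
  cand <- cand[order(d[cand], cand)]
  sort(c(i, head(cand, k)))
}

#' Spatially augment one signal matrix
#'
#' Produces a new sample in which column i is the time-point-wise mean of the
#' original columns in the neighbour set of node i. All neighbour sets are
#' applied to the original matrix (no sequential in-place updating), so the
#' output does not depend on node order.
#'
#' @param signals Numeric t x m matrix.
#' @param geometry An [atlas_geometry()] with `m` matching `ncol(signals)`.
#' @inheritParams build_neighbor_set
#' @return A t x m matrix of the same shape; with `k = 0` it equals the
#'   input exactly.
#' @export
spatial_augment_sample <- function(signals, geometry, k, r = 0.5) {
  signals <- as.matrix(signals)
  if (ncol(signals) != geometry$m) {
    abort(sprintf(
      "Signal matrix has %d columns but the atlas defines %d ROIs.",
      ncol(signals), geometry$m
    ))
  }
  out <- signals
  for (i in seq_len(geometry$m)) {
    members <- build_neighbor_set(i, geometry, k = k, r = r)
    if (length(members) > 1) {
      out[, i] <- rowMeans(signals[, members, drop = FALSE])
    }
  }
  out
}

#' Generate the spatial augmentation set of a cohort
#'
#' For each subject, one augmented sample is produced per neighbour count
#' k = 1, 2, ..., degree, so the output has `degree * nrow(cohort)` rows. An
#' augmentation degree of 4 therefore quadruples the training set. Augmented
#' rows carry provenance: `source_id` (the originating subject), `augment`
#' ("spatial") and `k`; labels are inherited.
#'
#' @param cohort A cohort tibble (`subject_id`, `label`, `signals`).
#' @param geometry An [atlas_geometry()].
#' @param degree Number of augmented samples per subject (`1 <= degree <=
#'   m - 1`), realized as the neighbour-count ladder k = 1..degree.
#' @param r Radius fraction in (0, 1), see [build_neighbor_set()].
#' @return A tibble of augmented samples with provenance columns. Augmented
#'   signals are not re-z-scored: Pearson correlation is shift/scale
#'   invariant, so downstream networks are unaffected.
#' @export
augment_spatial <- function(cohort, geometry, degree = 4, r = 0.5) {
  if (degree < 1) abort("`degree` must be >= 1.")
  if (degree > geometry$m - 1) {
    abort(sprintf(
      "`degree` (%d) cannot exceed m - 1 = %d.", degree, geometry$m - 1
    ))
  }
  grid <- tidyr::expand_grid(row = seq_len(nrow(cohort)), k = seq_len(degree))
  tibble(
    subject_id = sprintf("%s_s%d", cohort$subject_id[grid$row], grid$k),
    label = cohort$label[grid$row],
    signals = purrr::map2(grid$row, grid$k, function(ri, k) {
      spatial_augment_sample(cohort$signals[[ri]], geometry, k = k, r = r)
    }),
    source_id = cohort$subject_id[grid$row],
    augment = "spatial",
    k = grid$k
  )
}
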