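# Temporal augmentation: random discontinuous resampling of time points.
# Each augmented sample keeps l < t randomly chosen rows (without
# replacement, one shared index list across all ROIs) in ascending time
# order. In the spirit of jackknife resampling, correlations estimated from
# many such subsamples average toward the full-sample estimate.

#' Draw a random set of time-point indices
#'
#' Draws `l` distinct indices uniformly without replacement from `1..t`,
#' returned in ascending order. The draw is fully determined by `seed`.
#'
#' @param t Number of available time points.
#' @param l Number of indices to draw (`l_min <= l <= t`).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param l_min Minimum admissible `l`, guarding against subsamples too
#'   sparse to estimate correlations from. Default 1.
#' @return Sorted integer vector of length `l`.
#' @export
sample_time_indices <- function(t, l, seed, l_min = 1L) {
  if (l > t) abort(sprintf("Cannot draw l = %d from t = %d time points.", l, t))
  if (l < l_min) abort(sprintf("l = %d is below the floor l_min = %d.", l, l_min))
  withr::with_seed(as.integer(seed), sort(sample.int(t, l)))
}

#' Extract a temporally resampled sample
#'
#' Returns the row slice of the signal matrix at the given time indices. The
#' same index list is applied to every ROI column, preserving the
#' inter-regional alignment that Pearson correlation measures.
#'
#' @param signals Numeric t x m matrix.
#' @param indices Integer vector of row indices (each in `1..t`).
#' @return An `length(indices)` x m matrix.
#' @export
temporal_augment_sample <- function(signals, indices) {
  signals <- as.matrix(signals)
  if (any(indices < 1 | indices > nrow(signals))) {
    abort(sprintf(
      "Time index out of range 1..%d.", nrow(signals)
    ))
  }
  signals[indices, , drop = FALSE]
}

# Derives one sub-seed per (subject, replicate) pair from the master seed so
# that any draw can be reproduced in isolation; kept below 2^31.
derive_seed <- function(master, subject_index, replicate) {
  (as.double(master) * 2654435761 + subject_index * 97003 + replicate * 7919) %%
    2147483647
}

#' Generate the temporal augmentation set of a cohort
#'
#' Produces `degree` resampled copies of every subject (a temporal degree of
#' 100 yields a 100-fold larger training set). Each copy keeps
#' `l = ceiling(l_frac * t)` randomly selected, generally non-contiguous time
#' points. All draws derive from the single `seed` together with the subject
#' and replicate indices, so the full set is reproducible.
#'
#' @param cohort A cohort tibble.
#' @param degree Number of augmented samples per subject.
#' @param l_frac Fraction of time points kept per sample, in (0, 1];
#'   `l = ceiling(l_frac * t)` and l must stay below t.
#' @param l_min_frac Floor on the kept fraction (`l_min = ceiling(l_min_frac
#'   * t)`); guards against overly sparse subsamples.
#' @param seed Master integer seed.
#' @param vary_l If `TRUE`, each draw uses its own l sampled uniformly from
#'   `l_min..l`; by default l is fixed across draws.
#' @return A tibble of augmented samples with provenance columns
#'   `source_id`, `augment` ("temporal"), and `indices` (list-column of the
#'   kept time points); labels inherited.
#' @export
augment_temporal <- function(cohort, degree = 100, l_frac = 0.7,
                             l_min_frac = 0.5, seed = 1L, vary_l = FALSE) {
  if (degree < 1) abort("`degree` must be >= 1.")
  if (l_frac <= 0 || l_frac > 1) abort("`l_frac` must lie in (0, 1].")
  rows <- purrr::map(seq_len(nrow(cohort)), function(si) {
    x <- cohort$signals[[si]]
    t_len <- nrow(x)
    l <- ceiling(l_frac * t_len)
    l_min <- ceiling(l_min_frac * t_len)
    if (l >= t_len) l <- t_len - 1L
    if (l < l_min) {
      abort(sprintf(
        "Subject %s: l = %d below floor l_min = %d (t = %d).",
        cohort$subject_id[si], l, l_min, t_len
      ))
    }
    purrr::map(seq_len(degree), function(rep) {
      s <- derive_seed(seed, si, rep)
      l_use <- if (vary_l) {
        withr::with_seed(as.integer((s + 1) %% 2147483647),
                         sample(seq(l_min, l), 1))
      } else {
        l
      }
      idx <- sample_time_indices(t_len, l_use, seed = s, l_min = l_min)
      tibble(
        subject_id = sprintf("%s_t%d", cohort$subject_id[si], rep),
        label = cohort$label[si],
        signals = list(temporal_augment_sample(x, idx)),
        source_id = cohort$subject_id[si],
        augment = "temporal",
        indices = list(idx)
      )
    })
  })
  bind_rows(purrr::flatten(rows))
}
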