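# Synthetic cohorts: multivariate-normal ROI time series with
# group-dependent correlation structure on an atlas-like jittered 3-D grid.
# Pearson correlation is the analysis target, so second-order structure is
# the sufficient statistic to emulate; BOLD haemodynamics, autocorrelated
# noise and site effects are deliberately not modelled.

#' Generate an atlas-like geometry on a jittered 3-D grid
#'
#' Places m ROI centroids on a regular 3-D grid with the given spacing and
#' adds uniform jitter so distances are generic (no exact ties).
#'
#' @param m Number of ROIs.
#' @param spacing Grid spacing in mm (default 10).
#' @param jitter Uniform jitter half-width in mm (default `0.1 * spacing`).
#' @param seed Integer seed.
#' @return An [atlas_geometry()] with ROI names `ROI001`, `ROI002`, ...
#' @export
make_geometry <- function(m, spacing = 10, jitter = 0.1 * spacing, seed = 1L) {
  if (m < 2) abort("`m` must be >= 2.")
  side <- ceiling(m^(1 / 3))
  grid <- as.matrix(expand.grid(
    x = seq_len(side), y = seq_len(side), z = seq_len(side)
  ))[seq_len(m), , drop = FALSE]
  coords <- withr::with_seed(as.integer(seed), {
    grid * spacing + matrix(runif(3 * m, -jitter, jitter), m, 3)
  })
  atlas_geometry(sprintf("ROI%03d", seq_len(m)), coords)
}

#' Default planted-edge table
#'
#' Disjoint edges carrying group correlation differences from 0.4 to 0.6:
#' five edges when the atlas allows it (m >= 10), otherwise as many disjoint
#' pairs as fit. This is the planted-effect configuration used throughout
#' validation.
#'
#' @param m Number of ROIs (m >= 4).
#' @return Tibble with columns `i`, `j`, `delta`.
#' @export
default_planted_edges <- function(m = 30) {
  if (m < 4) abort("Need m >= 4 to plant disjoint edges.")
  n_edges <- min(5L, floor(m / 2))
  step <- floor(m / n_edges)
  tibble(
    i = 1 + step * (seq_len(n_edges) - 1),
    j = 2 + step * (seq_len(n_edges) - 1),
    delta = seq(0.4, 0.6, length.out = n_edges)
  )
}

# Per-class target correlation matrix: AR(1)-style base rho^|i-j| with the
# planted deltas scaled by (class index - 1) / (c - 1), so the first class
# is the base and the last carries the full delta.
class_correlation <- function(m, base_rho, planted, class_index, n_classes) {
  sigma <- base_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  if (!is.null(planted) && nrow(planted) > 0 && n_classes > 1) {
    scale_c <- (class_index - 1) / (n_classes - 1)
    for (e in seq_len(nrow(planted))) {
      v <- sigma[planted$i[e], planted$j[e]] + planted$delta[e] * scale_c
      if (abs(v) >= 1) {
        abort(sprintf(
          "Planted delta at edge (%d, %d) pushes correlation to %.2f (outside (-1, 1)).",
          planted$i[e], planted$j[e], v
        ))
      }
      sigma[planted$i[e], planted$j[e]] <- v
      sigma[planted$j[e], planted$i[e]] <- v
    }
  }
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf(
      "Target correlation matrix for class %d is not positive definite.",
      class_index
    ))
  }
  sigma
}

#' Simulate a synthetic cohort with planted group structure
#'
#' Each subject's t rows are independent draws from a zero-mean multivariate
#' normal with its class's target correlation matrix; independent white
#' noise of standard deviation `noise_sd` is added (attenuating observed
#' correlations by a factor `1 / (1 + noise_sd^2)`), and the signals are
#' z-scored per ROI, as real ROI series would be after preprocessing.
#' Classes differ only through the planted edges: class 1 is the base
#' structure and later classes carry a growing fraction of each `delta`
#' (the last class the full delta). With `planted = NULL` all classes share
#' one correlation matrix — the null cohort used for calibration checks.
#'
#' @param n_per_class Subjects per class (default 20).
#' @param m Number of ROIs (default 30).
#' @param t Time points per subject (default 137, a typical ROI-series
#'   length after scanner preprocessing).
#' @param classes Character vector of class names (default control/patient).
#' @param base_rho Base AR(1) correlation decay (default 0.1).
#' @param planted Tibble `i, j, delta` of planted edges, or `NULL` for a
#'   null cohort. Default [default_planted_edges()].
#' @param noise_sd White-noise standard deviation (default 0.5).
#' @param spacing,jitter Geometry parameters, see [make_geometry()].
#' @param seed Master integer seed.
#' @return A list with `cohort` (tibble), `geometry` ([atlas_geometry()])
#'   and `truth` (list: `planted`, `class_corr` — the per-class target
#'   matrices, `noise_sd`, `seed`).
#' @export
simulate_cohort <- function(n_per_class = 20, m = 30, t = 137,
                            classes = c("control", "patient"),
                            base_rho = 0.1,
                            planted = default_planted_edges(m),
                            noise_sd = 0.5, spacing = 10,
                            jitter = 0.1 * spacing, seed = 1L) {
  if (!is.null(planted)) {
    if (any(planted$i == planted$j)) {
      abort("Planted edges must have distinct endpoints.")
    }
  }
  n_classes <- length(classes)
  geometry <- make_geometry(m, spacing = spacing, jitter = jitter, seed = seed)
  class_corr <- purrr::map(seq_len(n_classes), function(ci) {
    class_correlation(m, base_rho, planted, ci, n_classes)
  })
  names(class_corr) <- classes

  ids <- labels <- character(0)
  signals <- list()
  for (ci in seq_len(n_classes)) {
    for (si in seq_len(n_per_class)) {
      id <- sprintf("%s%03d", substr(classes[ci], 1, 3), si)
      sub_seed <- as.integer(
        (as.double(seed) * 7919 + ci * 1299709 + si * 104729) %% 2147483647
      )
      x <- withr::with_seed(sub_seed, {
        MASS::mvrnorm(t, mu = rep(0, m), Sigma = class_corr[[ci]]) +
          matrix(rnorm(t * m, sd = noise_sd), t, m)
      })
      ids <- c(ids, id)
      labels <- c(labels, classes[ci])
      signals <- c(signals, list(x))
    }
  }
  cohort <- new_cohort(ids, signals, factor(labels, levels = classes),
                       normalize = TRUE)
  list(
    cohort = cohort,
    geometry = geometry,
    truth = list(planted = planted, class_corr = class_corr,
                 noise_sd = noise_sd, seed = as.integer(seed))
  )
}
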