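# Functional brain network estimation: the FBN of a sample is its m x m
# Pearson correlation matrix; the classifier feature vector is the upper
# triangle in row-major order (no feature selection, no transform).

#' Estimate a functional brain network by Pearson correlation
#'
#' @param signals Numeric n x m matrix (n >= 3 time points, m ROIs).
#' @return An m x m correlation matrix with unit diagonal, symmetric, all
#'   entries in \[-1, 1\].
#' @export
pearson_fbn <- function(signals) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 3) {
    abort(sprintf(
      "Need at least 3 time points to estimate correlations (got %d).",
      nrow(signals)
    ))
  }
  sds <- apply(signals, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "Constant signal at node %d: correlation undefined.", which(sds == 0)[1]
    ))
  }
  corr <- cor(signals)
  diag(corr) <- 1
  dimnames(corr) <- NULL
  corr
}

#' Edge index table for m nodes
#'
#' Enumerates the m(m-1)/2 upper-triangle edges in the row-major order used
#' by [fbn_vectorize()]: (1,2), (1,3), ..., (1,m), (2,3), ...
#'
#' @param m Number of nodes.
#' @return A tibble with columns `edge` (feature position), `i`, `j`
#'   (node indices, i < j).
#' @export
edge_index_table <- function(m) {
  idx <- which(lower.tri(diag(m)), arr.ind = TRUE)
  tibble(edge = seq_len(nrow(idx)), i = idx[, 2], j = idx[, 1])
}

#' Vectorize a functional brain network
#'
#' Flattens the strict upper triangle of a correlation matrix into the
#' length-m(m-1)/2 feature vector, row-major: (1,2), (1,3), ..., (2,3), ...
#' The diagonal is excluded (constant 1 carries no information).
#'
#' @param corr Symmetric m x m matrix.
#' @return Numeric vector of length `m * (m - 1) / 2`.
#' @seealso [fbn_devectorize()] for the exact inverse.
#' @export
fbn_vectorize <- function(corr) {
  corr <- as.matrix(corr)
  t(corr)[lower.tri(corr)]
}

#' Reconstruct a correlation matrix from its feature vector
#'
#' Exact inverse of [fbn_vectorize()]: rebuilds the symmetric m x m matrix
#' with unit diagonal.
#'
#' @param features Numeric vector of length m(m-1)/2.
#' @param m Number of nodes.
#' @return An m x m symmetric matrix with unit diagonal.
#' @export
fbn_devectorize <- function(features, m) {
  if (length(features) != m * (m - 1) / 2) {
    abort(sprintf(
      "Feature length %d does not match m = %d (expected %d).",
      length(features), m, m * (m - 1) / 2
    ))
  }
  corr <- diag(m)
  tc <- t(corr)
  tc[lower.tri(tc)] <- features
  corr <- t(tc)
  corr[lower.tri(corr)] <- t(corr)[lower.tri(corr)]
  corr
}

#' Compute the FBN feature matrix of a cohort
#'
#' Applies [pearson_fbn()] and [fbn_vectorize()] to every sample.
#'
#' @param cohort A cohort tibble.
#' @return Numeric matrix, one row per sample (rownames = subject ids), one
#'   column per edge.
#' @export
cohort_features <- function(cohort) {
  feats <- purrr::map(cohort$signals, function(x) fbn_vectorize(pearson_fbn(x)))
  out <- do.call(rbind, feats)
  rownames(out) <- cohort$subject_id
  out
}

#' Export a functional brain network
#'
#' Writes the correlation matrix as delimited text, an edge list TSV
#' (`roi_a, roi_b, weight`), or a BrainNet-Viewer `.edge` file (the square
#' matrix, whitespace-delimited, no names).
#'
#' @param corr m x m correlation matrix.
#' @param path Output path.
#' @param format One of "matrix", "edges", "brainnet".
#' @param roi_names Optional ROI names for the edge list.
#' @return `path`, invisibly.
#' @export
write_fbn <- function(corr, path, format = c("matrix", "edges", "brainnet"),
                      roi_names = NULL) {
  format <- match.arg(format)
  m <- nrow(corr)
  if (is.null(roi_names)) roi_names <- sprintf("ROI%03d", seq_len(m))
  if (format == "matrix") {
    readr::write_tsv(as.data.frame(corr), path, col_names = FALSE)
  } else if (format == "edges") {
    et <- edge_index_table(m)
    readr::write_tsv(
      tibble(
        roi_a = roi_names[et$i], roi_b = roi_names[et$j],
        weight = fbn_vectorize(corr)
      ),
      path
    )
  } else {
    utils::write.table(corr, path, sep = " ", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
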