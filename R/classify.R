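# Branch classifiers and tensor-score fusion. Both branches emit per-class
# probability vectors (a common nonnegative scale, required because fusion
# multiplies the two vectors); the fused feature is the z-scored flattened
# outer product, fed to a third classifier of the same kind.

#' Train a branch classifier on FBN feature vectors
#'
#' Supported kinds: `"svm"` (linear-kernel SVM with probability outputs),
#' `"rf"` (random forest, 500 trees) and `"nnet"` (one-hidden-layer neural
#' network with softmax outputs). All three expose per-class probabilities so
#' branch scores share a scale.
#'
#' @param features Numeric matrix, one sample per row.
#' @param labels Class labels (coerced to factor); at least 2 classes must be
#'   present.
#' @param kind One of "svm", "rf", "nnet".
#' @param seed Integer seed fixing any fit-time randomness (probability
#'   calibration, bootstrap, weight initialization).
#' @param ... Passed to the underlying fitter: e.g. `cost` for svm, `ntree`
#'   for rf (default 500), `size`/`maxit` for nnet (defaults 100 / 200).
#' @return A `branch_model` object recording the kind, the fitted model, the
#'   class order and the feature dimensionality.
#' @export
train_branch <- function(features, labels, kind = c("svm", "rf", "nnet"),
                         seed = 1L, ...) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) {
    abort("Training set contains a single class; need at least 2.")
  }
  if (length(labels) != nrow(features)) {
    abort("`labels` length must equal the number of feature rows.")
  }
  dots <- list(...)
  fit <- withr::with_seed(as.integer(seed), {
    switch(kind,
      svm = e1071::svm(
        features, labels,
        kernel = "linear", probability = TRUE, scale = FALSE,
        cost = dots$cost %||% 1, cachesize = 200
      ),
      rf = randomForest::randomForest(
        features, labels,
        ntree = dots$ntree %||% 500
      ),
      nnet = {
        size <- dots$size %||% 100
        y <- nnet::class.ind(labels)
        nnet::nnet(
          features, y,
          size = size, softmax = TRUE, trace = FALSE,
          maxit = dots$maxit %||% 200,
          MaxNWts = (ncol(features) + 1) * size + (size + 1) * ncol(y) + 1,
          decay = dots$decay %||% 1e-4
        )
      }
    )
  })
  structure(
    list(kind = kind, fit = fit, classes = levels(labels),
         n_features = ncol(features), seed = as.integer(seed)),
    class = "branch_model"
  )
}

#' @export
print.branch_model <- function(x, ...) {
  cat(sprintf(
    "<branch_model> kind = %s, %d classes (%s), %d features\n",
    x$kind, length(x$classes), paste(x$classes, collapse = ", "),
    x$n_features
  ))
  invisible(x)
}

#' Per-class probability scores from a branch classifier
#'
#' @param model A [train_branch()] model.
#' @param features Numeric matrix (or single vector) of FBN features with
#'   the training dimensionality.
#' @return Numeric matrix, one row per sample, one column per class in the
#'   model's recorded class order; rows are probabilities summing to 1.
#' @export
predict_scores <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    abort(sprintf(
      "Feature dimensionality %d does not match training dimensionality %d.",
      ncol(features), model$n_features
    ))
  }
  scores <- switch(model$kind,
    svm = {
      pr <- predict(model$fit, features, probability = TRUE)
      attr(pr, "probabilities")
    },
    rf = predict(model$fit, features, type = "prob"),
    nnet = {
      p <- predict(model$fit, features)
      if (is.null(colnames(p))) colnames(p) <- model$classes
      p
    }
  )
  scores <- scores[, model$classes, drop = FALSE]
  dimnames(scores) <- list(rownames(features), model$classes)
  scores
}

#' Fuse a spatial and a temporal score vector by tensor product
#'
#' Computes the outer product of the spatial-branch score vector with the
#' temporal-branch score vector, flattens it row-major (spatial index major:
#' entry (a-1)*c + b is `s_spatial[a] * s_temporal[b]`), and normalizes the
#' c^2 entries to mean 0 and standard deviation 1. A zero-variance product
#' (e.g. both branches uniform) yields the all-zero vector with a warning
#' rather than an error.
#'
#' @param s_spatial,s_temporal Numeric score vectors of the same length c.
#' @return Numeric fused vector of length c^2.
#' @export
fuse_scores <- function(s_spatial, s_temporal) {
  if (length(s_spatial) != length(s_temporal)) {
    abort("Branch score vectors must have the same length.")
  }
  if (!all(is.finite(s_spatial)) || !all(is.finite(s_temporal))) {
    abort("Branch scores must be finite.")
  }
  omega <- as.vector(t(outer(s_spatial, s_temporal)))
  s <- sd(omega)
  if (s == 0) {
    warn("Degenerate fused score (zero variance); returning all zeros.")
    return(rep(0, length(omega)))
  }
  (omega - mean(omega)) / s
}

# Row-wise fusion of two score matrices -> n x c^2 fused feature matrix.
fuse_score_matrix <- function(S_spatial, S_temporal) {
  n <- nrow(S_spatial)
  out <- t(vapply(
    seq_len(n),
    function(i) fuse_scores(S_spatial[i, ], S_temporal[i, ]),
    numeric(ncol(S_spatial)^2)
  ))
  rownames(out) <- rownames(S_spatial)
  out
}

#' Train the fusion classifier on fused score features
#'
#' Identical contract to [train_branch()] but on c^2-dimensional fused score
#' vectors.
#'
#' @inheritParams train_branch
#' @param fused Numeric matrix of fused score vectors (rows = samples).
#' @return A `branch_model`.
#' @export
train_fusion <- function(fused, labels, kind = c("svm", "rf", "nnet"),
                         seed = 1L, ...) {
  train_branch(fused, labels, kind = kind, seed = seed, ...)
}

#' Fit the full spatial-temporal augmentation classification scheme
#'
#' Trains the three classifiers of the STDAC scheme on a training cohort:
#' (1) the spatial branch on the original subjects plus their spatially
#' augmented samples (neighbour-count ladder k = 1..spatial_degree), (2) the
#' temporal branch on the originals plus `temporal_degree` random
#' discontinuous resamples per subject, and (3) the fusion classifier on the
#' z-scored outer products of the two branches' probability vectors for the
#' original (unaugmented) training subjects — mirroring the test-time
#' contract, where only original samples are scored.
#'
#' @param cohort Training cohort tibble (original subjects only).
#' @param geometry An [atlas_geometry()].
#' @param classifier Classifier kind for all three models: "svm", "rf" or
#'   "nnet".
#' @param spatial_degree Spatial augmentation degree (default 4).
#' @param temporal_degree Temporal augmentation degree (default 100).
#' @param r Spatial radius fraction (default 0.5).
#' @param l_frac,l_min_frac Temporal kept-fraction and its floor.
#' @param seed Master seed for augmentation draws and classifier fits.
#' @param include_original Include the original subjects in each branch's
#'   training set alongside the augmented samples (default `TRUE`;
#'   augmentation enlarges rather than replaces the training set).
#' @param ... Passed to [train_branch()].
#' @return An object of class `stdac_model` holding the three
#'   `branch_model`s, the class order and the configuration.
#' @export
stdac_fit <- function(cohort, geometry, classifier = c("svm", "rf", "nnet"),
                      spatial_degree = 4, temporal_degree = 100, r = 0.5,
                      l_frac = 0.7, l_min_frac = 0.5, seed = 1L,
                      include_original = TRUE, ...) {
  classifier <- match.arg(classifier)
  aug_s <- augment_spatial(cohort, geometry, degree = spatial_degree, r = r)
  aug_t <- augment_temporal(cohort, degree = temporal_degree, l_frac = l_frac,
                            l_min_frac = l_min_frac, seed = seed)
  train_s <- if (include_original) bind_rows(cohort, aug_s) else aug_s
  train_t <- if (include_original) bind_rows(cohort, aug_t) else aug_t

  X_orig <- cohort_features(cohort)
  model_s <- train_branch(cohort_features(train_s), train_s$label,
                          kind = classifier, seed = seed, ...)
  model_t <- train_branch(cohort_features(train_t), train_t$label,
                          kind = classifier, seed = seed + 1L, ...)
  fused <- fuse_score_matrix(
    predict_scores(model_s, X_orig),
    predict_scores(model_t, X_orig)
  )
  model_f <- train_fusion(fused, cohort$label, kind = classifier,
                          seed = seed + 2L, ...)
  structure(
    list(
      spatial = model_s, temporal = model_t, fusion = model_f,
      classes = model_f$classes,
      config = list(
        classifier = classifier, spatial_degree = spatial_degree,
        temporal_degree = temporal_degree, r = r, l_frac = l_frac,
        l_min_frac = l_min_frac, seed = as.integer(seed),
        include_original = include_original
      )
    ),
    class = "stdac_model"
  )
}

#' @export
print.stdac_model <- function(x, ...) {
  cat(sprintf(
    "<stdac_model> classifier = %s, classes: %s\n  spatial degree %d, temporal degree %d, r = %.2f, l_frac = %.2f\n",
    x$config$classifier, paste(x$classes, collapse = ", "),
    x$config$spatial_degree, x$config$temporal_degree, x$config$r,
    x$config$l_frac
  ))
  invisible(x)
}

#' Predict labels for original subjects with a fitted STDAC model
#'
#' Computes each subject's original-sample FBN features once, scores them
#' with both branch models, fuses the score pair, and classifies the fused
#' vector with the fusion model. Subjects are expected to be unaugmented:
#' the test-time contract scores original samples only.
#'
#' @param model A fitted [stdac_fit()] model.
#' @param cohort Cohort tibble of subjects to classify.
#' @return A tibble with `subject_id`, `.pred` (the predicted label) and one
#'   `.score_<class>` column per class (fusion-model probabilities).
#' @export
stdac_predict <- function(model, cohort) {
  X <- cohort_features(cohort)
  fused <- fuse_score_matrix(
    predict_scores(model$spatial, X),
    predict_scores(model$temporal, X)
  )
  scores <- predict_scores(model$fusion, fused)
  build_prediction_tibble(cohort$subject_id, scores, model$classes)
}

build_prediction_tibble <- function(subject_id, scores, classes) {
  pred <- classes[max.col(scores, ties.method = "first")]
  out <- tibble(
    subject_id = subject_id,
    .pred = factor(pred, levels = classes)
  )
  for (ci in seq_along(classes)) {
    out[[paste0(".score_", classes[ci])]] <- scores[, ci]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
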