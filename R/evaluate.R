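# Leakage-safe stratified k-fold cross-validation of the four schemes
# (original / sda / tda / stdac). Augmentation happens strictly inside each
# training fold; a sentinel aborts if any training sample's provenance
# traces to a test subject.

#' Stratified cross-validation folds
#'
#' Splits subjects into `n_folds` disjoint, approximately class-balanced
#' test folds. Deterministic given `seed`.
#'
#' @param labels Class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return List of length `n_folds`; each element has integer vectors
#'   `train` and `test`. Test folds partition `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < n_folds)) {
    small <- names(sizes)[which(sizes < n_folds)[1]]
    abort(sprintf(
      paste0(
        "Class '%s' has %d subjects, fewer than n_folds = %d. ",
        "Reduce the fold count or pool classes."
      ),
      small, sizes[[small]], n_folds
    ))
  }
  assign_fold <- withr::with_seed(as.integer(seed), {
    fold <- integer(length(labels))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
  purrr::map(seq_len(n_folds), function(f) {
    list(train = which(assign_fold != f), test = which(assign_fold == f))
  })
}

#' Abort if training data leaks information from test subjects
#'
#' The sentinel used inside every cross-validation fold: each training row's
#' source subject (its `source_id` provenance if augmented, otherwise its
#' own `subject_id`) must be disjoint from the test subject ids.
#'
#' @param train_cohort Training cohort tibble (original and/or augmented
#'   rows).
#' @param test_ids Character vector of test subject ids.
#' @return `TRUE` invisibly; aborts on any overlap.
#' @export
assert_no_leakage <- function(train_cohort, test_ids) {
  sources <- train_cohort$subject_id
  if ("source_id" %in% names(train_cohort)) {
    has_src <- !is.na(train_cohort$source_id)
    sources[has_src] <- train_cohort$source_id[has_src]
  }
  bad <- intersect(unique(sources), test_ids)
  if (length(bad) > 0) {
    abort(sprintf(
      "Leakage detected: training samples derive from test subject(s) %s.",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Classification metrics from predicted labels and scores
#'
#' Accuracy and per-class precision/recall are reported as percentages; for
#' binary tasks a full ROC curve (score thresholds on the second class) and
#' its trapezoidal AUC are included. A class that is never predicted gets
#' precision 0 (with a warning).
#'
#' @param truth True labels (factor or coercible).
#' @param pred Predicted labels.
#' @param scores Optional numeric score matrix (columns = classes, matching
#'   `classes` order) for the ROC.
#' @param classes Class order; defaults to the levels of `truth`.
#' @return A list with `accuracy` (%), `by_class` (tibble: class, precision,
#'   recall, n), `macro_precision`, `macro_recall`, and for binary scored
#'   input `roc` (tibble: threshold, fpr, tpr) and `auc`.
#' @export
compute_metrics <- function(truth, pred, scores = NULL, classes = NULL) {
  truth <- factor(truth)
  if (is.null(classes)) classes <- levels(truth)
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  if (length(truth) != length(pred)) {
    abort("`truth` and `pred` must have equal length.")
  }
  cm <- table(truth = truth, pred = pred)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  prec <- rec <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    tp <- cm[ci, ci]
    predicted <- sum(cm[, ci])
    actual <- sum(cm[ci, ])
    if (predicted == 0) {
      warn(sprintf(
        "Class '%s' was never predicted; precision reported as 0.",
        classes[ci]
      ))
      prec[ci] <- 0
    } else {
      prec[ci] <- 100 * tp / predicted
    }
    rec[ci] <- if (actual == 0) NA_real_ else 100 * tp / actual
  }
  out <- list(
    accuracy = acc,
    by_class = tibble(
      class = classes, precision = prec, recall = rec,
      n = as.integer(rowSums(cm))
    ),
    macro_precision = mean(prec),
    macro_recall = mean(rec, na.rm = TRUE),
    confusion = cm
  )
  if (!is.null(scores) && length(classes) == 2) {
    sc <- as.matrix(scores)[, 2]
    roc <- roc_points(truth == classes[2], sc)
    out$roc <- roc
    out$auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  out
}

# ROC by sweeping every observed score as a threshold (predict positive when
# score >= threshold), plus the degenerate endpoints.
roc_points <- function(is_pos, score) {
  thr <- c(Inf, sort(unique(score), decreasing = TRUE))
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  tpr <- vapply(thr, function(th) sum(score >= th & is_pos) / n_pos, 0)
  fpr <- vapply(thr, function(th) sum(score >= th & !is_pos) / n_neg, 0)
  tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
}

#' Cross-validate one or several augmentation schemes
#'
#' Runs leakage-safe stratified k-fold cross-validation for the requested
#' schemes, sharing branch models across schemes within each fold (the
#' temporal branch trained for `tda` is the same model the `stdac` fusion
#' uses, etc.). Within each fold, augmentation is applied to the training
#' subjects only; test subjects are always evaluated as original samples.
#' Schemes: `original` (single classifier on original FBN features), `sda`
#' (spatial branch only), `tda` (temporal branch only), `stdac` (both
#' branches plus tensor-score fusion).
#'
#' @param cohort Cohort tibble of original subjects.
#' @param geometry An [atlas_geometry()].
#' @param schemes Character vector, subset of
#'   `c("original", "sda", "tda", "stdac")`.
#' @param classifier Classifier kind, see [train_branch()].
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Master seed; fold assignment, temporal draws and classifier
#'   fits all derive from it.
#' @param spatial_degree,temporal_degree,r,l_frac,l_min_frac Augmentation
#'   settings, see [stdac_fit()].
#' @param include_original Include original subjects in branch training
#'   sets (default `TRUE`).
#' @param ... Passed to [train_branch()].
#' @return A named list of `fbn_cv` objects, one per scheme (see
#'   [run_cv()] for their contents).
#' @export
evaluate_schemes <- function(cohort, geometry,
                             schemes = c("original", "sda", "tda", "stdac"),
                             classifier = c("svm", "rf", "nnet"),
                             folds = 10, seed = 1L,
                             spatial_degree = 4, temporal_degree = 100,
                             r = 0.5, l_frac = 0.7, l_min_frac = 0.5,
                             include_original = TRUE, ...) {
  classifier <- match.arg(classifier)
  schemes <- match.arg(schemes, several.ok = TRUE)
  classes <- levels(cohort$label)
  fold_list <- stratified_folds(cohort$label, n_folds = folds, seed = seed)

  need_spatial <- any(schemes %in% c("sda", "stdac"))
  need_temporal <- any(schemes %in% c("tda", "stdac"))
  preds <- setNames(vector("list", length(schemes)), schemes)

  for (f in seq_along(fold_list)) {
    tr <- fold_list[[f]]$train
    te <- fold_list[[f]]$test
    train <- cohort[tr, ]
    test <- cohort[te, ]
    fold_seed <- as.integer((seed + 104729 * f) %% 2147483647)
    X_test <- cohort_features(test)
    X_train <- cohort_features(train)

    model_s <- model_t <- NULL
    if (need_spatial) {
      aug_s <- augment_spatial(train, geometry, degree = spatial_degree, r = r)
      set_s <- if (include_original) bind_rows(train, aug_s) else aug_s
      assert_no_leakage(set_s, test$subject_id)
      model_s <- train_branch(cohort_features(set_s), set_s$label,
                              kind = classifier, seed = fold_seed, ...)
    }
    if (need_temporal) {
      aug_t <- augment_temporal(train, degree = temporal_degree,
                                l_frac = l_frac, l_min_frac = l_min_frac,
                                seed = fold_seed)
      set_t <- if (include_original) bind_rows(train, aug_t) else aug_t
      assert_no_leakage(set_t, test$subject_id)
      model_t <- train_branch(cohort_features(set_t), set_t$label,
                              kind = classifier, seed = fold_seed + 1L, ...)
    }

    for (sch in schemes) {
      scores <- switch(sch,
        original = {
          m0 <- train_branch(X_train, train$label, kind = classifier,
                             seed = fold_seed + 2L, ...)
          predict_scores(m0, X_test)
        },
        sda = predict_scores(model_s, X_test),
        tda = predict_scores(model_t, X_test),
        stdac = {
          fused_tr <- fuse_score_matrix(
            predict_scores(model_s, X_train),
            predict_scores(model_t, X_train)
          )
          mf <- train_fusion(fused_tr, train$label, kind = classifier,
                             seed = fold_seed + 3L, ...)
          fused_te <- fuse_score_matrix(
            predict_scores(model_s, X_test),
            predict_scores(model_t, X_test)
          )
          predict_scores(mf, fused_te)
        }
      )
      ptab <- build_prediction_tibble(test$subject_id, scores, classes)
      ptab$fold <- f
      ptab$truth <- test$label
      preds[[sch]] <- bind_rows(preds[[sch]], ptab)
    }
  }

  out <- purrr::imap(preds, function(ptab, sch) {
    score_mat <- as.matrix(ptab[paste0(".score_", classes)])
    metrics <- compute_metrics(ptab$truth, ptab$.pred, scores = score_mat,
                               classes = classes)
    fold_acc <- ptab %>%
      group_by(.data$fold) %>%
      summarise(accuracy = 100 * mean(.data$.pred == .data$truth),
                .groups = "drop")
    structure(
      list(
        scheme = sch, classifier = classifier, n_folds = length(fold_list),
        seed = as.integer(seed),
        accuracy = mean(fold_acc$accuracy),
        fold_accuracy = fold_acc,
        metrics = metrics,
        predictions = ptab,
        config = list(
          spatial_degree = spatial_degree, temporal_degree = temporal_degree,
          r = r, l_frac = l_frac, l_min_frac = l_min_frac,
          include_original = include_original
        )
      ),
      class = "fbn_cv"
    )
  })
  out[schemes]
}

#' Cross-validate a single scheme
#'
#' Convenience wrapper around [evaluate_schemes()] for one scheme.
#'
#' @inheritParams evaluate_schemes
#' @param scheme One of "original", "sda", "tda", "stdac".
#' @return An `fbn_cv` object: per-fold and mean accuracy (%), pooled
#'   per-class precision/recall (%), the per-subject prediction table, and
#'   for binary tasks the ROC curve and AUC. Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect it.
#' @export
run_cv <- function(cohort, geometry,
                   scheme = c("original", "sda", "tda", "stdac"),
                   classifier = c("svm", "rf", "nnet"), folds = 10,
                   seed = 1L, ...) {
  scheme <- match.arg(scheme)
  evaluate_schemes(cohort, geometry, schemes = scheme,
                   classifier = classifier, folds = folds, seed = seed,
                   ...)[[scheme]]
}

#' @export
print.fbn_cv <- function(x, ...) {
  cat(sprintf(
    "<fbn_cv> scheme = %s, classifier = %s, %d-fold CV (seed %d)\n",
    x$scheme, x$classifier, x$n_folds, x$seed
  ))
  cat(sprintf("  mean accuracy: %.2f%%\n", x$accuracy))
  if (!is.null(x$metrics$auc)) cat(sprintf("  AUC: %.3f\n", x$metrics$auc))
  print(x$metrics$by_class)
  invisible(x)
}

#' @rdname run_cv
#' @param x An `fbn_cv` object.
#' @exportS3Method generics::tidy
tidy.fbn_cv <- function(x, ...) {
  x$metrics$by_class %>%
    tidyr::pivot_longer(c("precision", "recall"),
                        names_to = "metric", values_to = "value") %>%
    mutate(scheme = x$scheme, .before = 1)
}

#' @rdname run_cv
#' @exportS3Method generics::glance
glance.fbn_cv <- function(x, ...) {
  tibble(
    scheme = x$scheme, classifier = x$classifier, n_folds = x$n_folds,
    accuracy = x$accuracy,
    macro_precision = x$metrics$macro_precision,
    macro_recall = x$metrics$macro_recall,
    auc = if (is.null(x$metrics$auc)) NA_real_ else x$metrics$auc
  )
}

#' @rdname run_cv
#' @param object An `fbn_cv` object.
#' @exportS3Method ggplot2::autoplot
autoplot.fbn_cv <- function(object, ...) {
  if (!is.null(object$metrics$roc)) {
    ggplot2::ggplot(object$metrics$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::coord_equal() +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("%s: ROC (AUC = %.3f)", object$scheme,
                        object$metrics$auc)
      )
  } else {
    ggplot2::ggplot(object$fold_accuracy,
                    ggplot2::aes(factor(.data$fold), .data$accuracy)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "Fold", y = "Accuracy (%)",
                    title = sprintf("%s: per-fold accuracy", object$scheme))
  }
}
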