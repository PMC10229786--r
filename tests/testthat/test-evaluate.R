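test_that("stratified folds partition the cohort with balanced classes", {
  labels <- rep(c("nc", "ad"), each = 10)
  folds <- stratified_folds(labels, n_folds = 10, seed = 1)
  expect_length(folds, 10)
  test_sets <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(test_sets), 1:20)
  expect_equal(sum(lengths(test_sets)), 20)
  for (f in folds) {
    expect_length(f$test, 2)
    expect_setequal(sort(unique(labels[f$test])), c("ad", "nc"))
    expect_setequal(c(f$train, f$test), 1:20)
  }
  expect_identical(folds, stratified_folds(labels, n_folds = 10, seed = 1))
  expect_false(identical(folds, stratified_folds(labels, n_folds = 10, seed = 2)))
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 15)), n_folds = 10),
               "fewer than")
})

test_that("the leakage sentinel passes clean folds and catches test-derived training rows", {
  coh <- noise_cohort(n = 6, m = 8, t = 25, seed = 3L)
  geo <- random_geometry(8, seed = 3L)
  train <- coh[1:4, ]
  test_ids <- coh$subject_id[5:6]
  aug <- augment_spatial(train, geo, degree = 2)
  expect_true(assert_no_leakage(dplyr::bind_rows(train, aug), test_ids))

  # corrupt the fold: an augmented sample derived from a test subject
  bad <- augment_spatial(coh[5, ], geo, degree = 1)
  expect_error(
    assert_no_leakage(dplyr::bind_rows(train, aug, bad), test_ids),
    "Leakage.*sub05"
  )
  # an original test row smuggled into training is equally fatal
  expect_error(assert_no_leakage(dplyr::bind_rows(train, coh[6, ]), test_ids),
               "Leakage")
})

test_that("classification metrics match their defining formulas", {
  # all correct
  m <- compute_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(m$accuracy, 100)
  expect_equal(m$by_class$precision, c(100, 100))
  expect_equal(m$by_class$recall, c(100, 100))

  # TP = 3, FP = 1, FN = 2 for the positive class
  truth <- c(rep("pos", 5), rep("neg", 4))
  pred <- c("pos", "pos", "pos", "neg", "neg", "neg", "neg", "neg", "pos")
  m <- compute_metrics(truth, pred, classes = c("neg", "pos"))
  expect_equal(m$by_class$precision[m$by_class$class == "pos"], 75)
  expect_equal(m$by_class$recall[m$by_class$class == "pos"], 60)

  # perfectly separating scores give AUC 1 and a full ROC sweep
  truth2 <- factor(rep(c("neg", "pos"), each = 5), levels = c("neg", "pos"))
  scores <- cbind(neg = seq(0.9, 0.1, length.out = 10),
                  pos = seq(0.1, 0.9, length.out = 10))
  m2 <- compute_metrics(truth2,
                        ifelse(scores[, 2] > 0.5, "pos", "neg"),
                        scores = scores, classes = c("neg", "pos"))
  expect_equal(m2$auc, 1)
  expect_equal(min(m2$roc$fpr), 0)
  expect_equal(max(m2$roc$tpr), 1)

  # a never-predicted class reports precision 0 with a warning
  expect_warning(
    m3 <- compute_metrics(c("a", "b"), c("a", "a"), classes = c("a", "b")),
    "never predicted"
  )
  expect_equal(m3$by_class$precision[2], 0)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5L, {
    truth <- factor(rep(c("neg", "pos"), each = 30), levels = c("neg", "pos"))
    score <- rnorm(60, mean = rep(c(0, 1), each = 30))
    m <- compute_metrics(truth, ifelse(score > 0.5, "pos", "neg"),
                         scores = cbind(neg = -score, pos = score),
                         classes = c("neg", "pos"))
    ref <- suppressMessages(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
    expect_equal(m$auc, as.numeric(ref), tolerance = 1e-10)
  })
})

test_that("accuracy equals the label-frequency-weighted mean of per-class recall", {
  for (s in 1:20) {
    cm <- withr::with_seed(s, {
      k <- sample(2:4, 1)
      n <- 60
      truth <- sample(letters[1:k], n, replace = TRUE)
      pred <- ifelse(runif(n) < 0.6, truth, sample(letters[1:k], n, replace = TRUE))
      list(truth = truth, pred = pred, k = k)
    })
    m <- suppressWarnings(
      compute_metrics(factor(cm$truth, levels = letters[1:cm$k]),
                      factor(cm$pred, levels = letters[1:cm$k]))
    )
    w <- m$by_class$n / sum(m$by_class$n)
    rec <- ifelse(is.na(m$by_class$recall), 0, m$by_class$recall)
    expect_equal(m$accuracy, sum(w * rec), tolerance = 1e-10)
  }
})

test_that("scheme cross-validation runs leakage-safe with shared branches", {
  sim <- simulate_cohort(n_per_class = 8, m = 10, t = 60, seed = 13)
  res <- evaluate_schemes(sim$cohort, sim$geometry,
                          classifier = "svm", folds = 4, seed = 3,
                          spatial_degree = 2, temporal_degree = 5)
  expect_named(res, c("original", "sda", "tda", "stdac"))
  for (r in res) {
    expect_s3_class(r, "fbn_cv")
    expect_gte(r$accuracy, 0)
    expect_lte(r$accuracy, 100)
    expect_equal(nrow(r$predictions), 16)
    # test folds partition the cohort
    expect_setequal(r$predictions$subject_id, sim$cohort$subject_id)
    expect_equal(r$n_folds, 4)
    expect_gte(r$metrics$auc, 0)
    expect_lte(r$metrics$auc, 1)
  }
  # single-scheme wrapper agrees with the joint run under the same seed
  solo <- run_cv(sim$cohort, sim$geometry, scheme = "original",
                 classifier = "svm", folds = 4, seed = 3,
                 spatial_degree = 2, temporal_degree = 5)
  expect_equal(solo$accuracy, res$original$accuracy)
  expect_identical(solo$predictions$.pred, res$original$predictions$.pred)
})

test_that("tidy, glance and autoplot summarise cross-validation results", {
  sim <- simulate_cohort(n_per_class = 6, m = 8, t = 50, seed = 17)
  r <- run_cv(sim$cohort, sim$geometry, scheme = "original",
              classifier = "svm", folds = 3, seed = 2)
  td <- tidy(r)
  expect_true(all(c("scheme", "class", "metric", "value") %in% names(td)))
  expect_equal(nrow(td), 4)  # 2 classes x precision/recall
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$accuracy, r$accuracy)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
})
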