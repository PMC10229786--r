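# Separable toy feature set: class b shifted on the first few features.
separable_features <- function(n = 40, p = 12, shift = 3, seed = 1L,
                               classes = c("a", "b")) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p, sd = 0.5), n, p)
    y <- factor(rep_len(classes, n))
    for (ci in seq_along(classes)[-1]) {
      x[y == classes[ci], seq_len(3)] <-
        x[y == classes[ci], seq_len(3)] + shift * (ci - 1)
    }
    list(x = x, y = y)
  })
}

test_that("branch classifiers separate a separable toy set and emit probability vectors", {
  fx <- separable_features()
  for (kind in c("svm", "rf", "nnet")) {
    model <- train_branch(fx$x, fx$y, kind = kind, seed = 3, size = 5)
    scores <- predict_scores(model, fx$x)
    expect_equal(dim(scores), c(40, 2))
    expect_equal(colnames(scores), c("a", "b"))
    expect_true(all(is.finite(scores)))
    expect_equal(rowSums(scores), rep(1, 40), tolerance = 1e-6)
    pred <- colnames(scores)[max.col(scores)]
    expect_equal(pred, as.character(fx$y))
  }
})

test_that("four-class training yields length-4 score vectors", {
  fx <- separable_features(n = 80, shift = 4, classes = c("nc", "emci", "lmci", "ad"))
  model <- train_branch(fx$x, fx$y, kind = "svm", seed = 1)
  scores <- predict_scores(model, fx$x[1:6, ])
  expect_equal(ncol(scores), 4)
  expect_setequal(colnames(scores), c("nc", "emci", "lmci", "ad"))
})

test_that("training is deterministic under a fixed seed", {
  fx <- separable_features(shift = 1)
  for (kind in c("svm", "rf", "nnet")) {
    s1 <- predict_scores(train_branch(fx$x, fx$y, kind = kind, seed = 11, size = 4),
                         fx$x)
    s2 <- predict_scores(train_branch(fx$x, fx$y, kind = kind, seed = 11, size = 4),
                         fx$x)
    expect_identical(s1, s2)
  }
})

test_that("single-class training sets and dimension mismatches are fatal", {
  fx <- separable_features()
  expect_error(train_branch(fx$x, rep("a", 40), kind = "svm"), "single class")
  model <- train_branch(fx$x, fx$y, kind = "svm")
  expect_error(predict_scores(model, fx$x[, 1:5]), "dimensionality")
})

test_that("relabelling classes permutes score columns consistently", {
  fx <- separable_features(seed = 9)
  m1 <- train_branch(fx$x, fx$y, kind = "svm", seed = 2)
  relabel <- factor(ifelse(fx$y == "a", "zz", "aa"))
  m2 <- train_branch(fx$x, relabel, kind = "svm", seed = 2)
  s1 <- predict_scores(m1, fx$x[1:8, ])
  s2 <- predict_scores(m2, fx$x[1:8, ])
  expect_equal(unname(s1[, "a"]), unname(s2[, "zz"]), tolerance = 1e-6)
  expect_equal(unname(s1[, "b"]), unname(s2[, "aa"]), tolerance = 1e-6)
})

test_that("score fusion equals the outer-product-plus-z-score oracle", {
  # worked example: pre-normalization tensor entries
  pre <- as.vector(t(outer(c(0.8, 0.2), c(0.6, 0.4))))
  expect_equal(pre, c(0.48, 0.32, 0.12, 0.08))
  expect_equal(fuse_scores(c(0.8, 0.2), c(0.6, 0.4)),
               fuse_oracle(c(0.8, 0.2), c(0.6, 0.4)))

  for (s in 1:50) {
    c_len <- sample(2:5, 1)
    s1 <- withr::with_seed(s, abs(rnorm(c_len)))
    s2 <- withr::with_seed(s + 1000, abs(rnorm(c_len)))
    omega <- fuse_scores(s1, s2)
    expect_length(omega, c_len^2)
    expect_equal(omega, fuse_oracle(s1, s2))
    expect_equal(mean(omega), 0, tolerance = 1e-8)
    expect_equal(sd(omega), 1, tolerance = 1e-8)
  }
})

test_that("one-hot fusion places a single nonzero pre-normalization entry", {
  c_len <- 4
  for (a in 1:c_len) {
    for (b in 1:c_len) {
      e_a <- as.numeric(seq_len(c_len) == a)
      e_b <- as.numeric(seq_len(c_len) == b)
      pre <- as.vector(t(outer(e_a, e_b)))
      expect_equal(sum(pre != 0), 1)
      expect_equal(which(pre != 0), (a - 1) * c_len + b)
      expect_length(fuse_scores(e_a, e_b), 16)
    }
  }
})

test_that("the pre-normalization fused tensor is the rank-1 outer product", {
  s1 <- c(0.5, 0.3, 0.2)
  s2 <- c(0.1, 0.6, 0.3)
  pre <- matrix(as.vector(t(outer(s1, s2))), 3, 3, byrow = TRUE)
  expect_equal(pre, s1 %*% t(s2))
  expect_equal(qr(pre)$rank, 1)
})

test_that("degenerate constant score products fuse to zeros with a warning", {
  expect_warning(omega <- fuse_scores(c(0.5, 0.5), c(0.5, 0.5)), "Degenerate")
  expect_equal(omega, rep(0, 4))
  expect_error(fuse_scores(c(1, 0), c(1, 0, 0)), "same length")
})

test_that("the fused pipeline prediction equals the manual composition of its stages", {
  sim <- simulate_cohort(n_per_class = 6, m = 10, t = 50, seed = 21)
  fit <- stdac_fit(sim$cohort, sim$geometry, classifier = "svm",
                   spatial_degree = 2, temporal_degree = 4, seed = 5)
  pred <- stdac_predict(fit, sim$cohort)
  expect_true(all(pred$.pred %in% levels(sim$cohort$label)))

  X <- cohort_features(sim$cohort)
  fused <- t(sapply(seq_len(nrow(X)), function(i) {
    fuse_scores(predict_scores(fit$spatial, X[i, , drop = FALSE])[1, ],
                predict_scores(fit$temporal, X[i, , drop = FALSE])[1, ])
  }))
  manual <- predict_scores(fit$fusion, fused)
  expect_equal(unname(as.matrix(pred[paste0(".score_", fit$classes)])),
               unname(manual), tolerance = 1e-9)
})

test_that("fusion on separable branches is at least as accurate as either branch in training", {
  sim <- simulate_cohort(n_per_class = 10, m = 12, t = 80, seed = 31)
  fit <- stdac_fit(sim$cohort, sim$geometry, classifier = "svm",
                   spatial_degree = 2, temporal_degree = 6, seed = 2)
  X <- cohort_features(sim$cohort)
  truth <- sim$cohort$label
  acc <- function(scores) {
    mean(fit$classes[max.col(scores, ties.method = "first")] == truth)
  }
  branch_best <- max(acc(predict_scores(fit$spatial, X)),
                     acc(predict_scores(fit$temporal, X)))
  fused_acc <- mean(stdac_predict(fit, sim$cohort)$.pred == truth)
  expect_gte(fused_acc, branch_best)
})
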