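test_that("RR threshold labelling follows the two regimes", {
  pairs <- data.frame(rr = c(1.43, 0, 0.5, 1, 8861.6))
  expect_equal(label_pairs(pairs, 1), c(1L, 0L, 0L, 1L, 1L))
  expect_equal(label_pairs(pairs, 0), c(1L, 0L, 1L, 1L, 1L))
})

test_that("stratified folds partition the data and are seed-reproducible", {
  labels <- c(rep(1L, 20), rep(0L, 20))
  folds <- stratified_kfold(labels, k = 10, seed = 5)
  expect_length(folds, 10)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(vapply(test_sets, function(te) {
    sum(labels[te] == 1) == 2 && sum(labels[te] == 0) == 2
  }, logical(1))))
  all_test <- sort(unlist(test_sets))
  expect_equal(all_test, seq_along(labels))           # disjoint cover
  expect_identical(folds, stratified_kfold(labels, k = 10, seed = 5))
  expect_false(identical(folds, stratified_kfold(labels, k = 10, seed = 6)))
  expect_error(stratified_kfold(c(1L, rep(0L, 20)), k = 10, seed = 1), ">= k")
})

test_that("every classifier kind separates a linearly separable toy set", {
  set.seed(41)
  m <- 5
  x <- rbind(matrix(1, 20, m), matrix(-1, 20, m)) +
    matrix(stats::rnorm(40 * m, sd = 0.05), 40, m)
  y <- c(rep(1L, 20), rep(0L, 20))
  for (kind in c("svm_linear", "svm_rbf", "svm_poly", "random_forest")) {
    model <- train_classifier(x, y, classifier_config(kind, seed = 2))
    pred <- predict_scores(model, x)
    expect_equal(pred$label, y, info = kind)
    expect_equal(roc_auc(pred$score, y), 1, info = kind)
  }
  expect_error(train_classifier(x, rep(1L, 40), classifier_config()), "single class")
  # duplicated rows with consistent labels are fine
  model <- train_classifier(rbind(x, x), c(y, y), classifier_config("svm_rbf"))
  expect_length(predict_scores(model, x)$label, 40)
})

test_that("classifier config records the optimized hyperparameters", {
  cfg <- classifier_config("svm_rbf")
  expect_equal(cfg$C, 3.5)
  expect_equal(cfg$gamma, 1.06)
  expect_equal(classifier_config("svm_poly")$degree, 4L)
  expect_equal(classifier_config("random_forest")$n_trees, 100L)
  model <- train_classifier(matrix(stats::rnorm(40), 20, 2),
                            rep(c(0L, 1L), 10), cfg)
  expect_equal(model$config$C, 3.5)
  expect_equal(model$config$gamma, 1.06)
})

test_that("evaluation metrics match their closed forms", {
  predicted <- c(rep(1L, 10), rep(0L, 10))
  truth <- c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8))
  scores <- seq(1, 0.05, by = -0.05)
  m <- evaluate_predictions(scores, predicted, truth)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(8, 2, 2, 8))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.8)

  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)  # all ties -> 0.5

  expect_warning(m1 <- evaluate_predictions(c(0.2, 0.9), c(0L, 1L), c(1L, 1L)),
                 "single class")
  expect_true(is.na(m1$roc_auc))
  expect_equal(m1$recall, 0.5)
})

test_that("ROC AUC equals the Mann-Whitney pair statistic on random scores", {
  set.seed(43)
  for (trial in 1:60) {
    n <- sample(6:20, 1)
    truth <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(scores, truth), oracle_auc(scores, truth))
  }
})

test_that("metrics are invariant under duplication of the test set", {
  set.seed(44)
  scores <- stats::runif(30)
  predicted <- as.integer(scores > 0.5)
  truth <- sample(0:1, 30, replace = TRUE)
  m1 <- evaluate_predictions(scores, predicted, truth)
  m2 <- evaluate_predictions(rep(scores, 2), rep(predicted, 2), rep(truth, 2))
  for (f in c("precision", "recall", "f1", "accuracy", "roc_auc")) {
    expect_equal(m1[[f]], m2[[f]], info = f)
  }
})

test_that("roc_points starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(45)
  scores <- stats::runif(25)
  truth <- sample(0:1, 25, replace = TRUE, prob = c(0.4, 0.6))
  pts <- roc_points(scores, truth)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("cross-validation is deterministic and standardizes without leakage", {
  set.seed(46)
  m <- 4
  x <- rbind(matrix(2, 30, m), matrix(-2, 30, m)) +
    matrix(stats::rnorm(60 * m), 60, m)
  y <- c(rep(1L, 30), rep(0L, 30))
  cv1 <- cross_validate(x, y, classifier_config("svm_rbf"), k = 5, seed = 3)
  cv2 <- cross_validate(x, y, classifier_config("svm_rbf"), k = 5, seed = 3)
  expect_identical(cv1$folds, cv2$folds)
  expect_gt(cv1$summary[["roc_auc"]], 0.9)

  # shuffled labels: no signal should survive (no-leakage check)
  set.seed(47)
  yshuf <- sample(y)
  cvs <- cross_validate(x, yshuf, classifier_config("svm_rbf"), k = 5, seed = 3)
  expect_lt(abs(cvs$summary[["roc_auc"]] - 0.5), 0.15)
})

test_that("paired significance handles degenerate and regular inputs", {
  a <- c(0.8, 0.82, 0.85, 0.9, 0.78)
  expect_equal(paired_significance(a, a), 1)
  expect_equal(paired_significance(a, a - 0.05), 0)   # zero-variance shift
  b <- a - c(0.05, 0.04, 0.06, 0.05, 0.03)
  # agreement with the closed-form paired t statistic
  d <- a - b
  tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p_manual <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  expect_equal(paired_significance(a, b), p_manual, tolerance = 1e-12)
  expect_error(paired_significance(a, a[1:3]), "equal length")
})
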