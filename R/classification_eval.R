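#' Classifier configuration
#'
#' Bundles the classifier kind and its hyperparameters. The defaults are
#' the optimized values used throughout: SVM cost C = 3.5, RBF gamma =
#' 1.06, polynomial degree 4 (kernel (<x, x'> + 1)^d), 100 trees for the
#' random forest.
#'
#' @param kind One of `"svm_rbf"`, `"svm_linear"`, `"svm_poly"`,
#'   `"random_forest"`.
#' @param C SVM cost parameter.
#' @param gamma RBF kernel width.
#' @param degree Polynomial kernel degree.
#' @param n_trees Number of random-forest trees.
#' @param seed Integer seed (used by the random forest).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm_rbf", "svm_linear", "svm_poly",
                                       "random_forest"),
                              C = 3.5, gamma = 1.06, degree = 4L,
                              n_trees = 100L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(C > 0, gamma > 0, degree >= 1, n_trees >= 1)
  structure(list(kind = kind, C = C, gamma = gamma, degree = as.integer(degree),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Label disease pairs by a relative-risk threshold
#'
#' At threshold 0 only pairs with RR exactly 0 are non-comorbid (label 1
#' iff rr > 0); at any positive threshold t, label 1 iff rr >= t. The two
#' regimes used in practice are t = 0 and t = 1.
#'
#' @param pairs Data frame with an `rr` column.
#' @param threshold Non-negative RR threshold.
#' @return Integer vector of 0/1 labels aligned with `pairs` rows.
#' @export
label_pairs <- function(pairs, threshold) {
  rr <- pairs$rr
  if (threshold > 0) as.integer(rr >= threshold) else as.integer(rr > 0)
}

#' Stratified k-fold splits
#'
#' Positives and negatives are shuffled and split independently into k
#' near-equal subsets; test fold i is the union of positive subset i and
#' negative subset i, so every fold keeps (approximately) the overall
#' class balance. Folds are disjoint and cover all observations.
#'
#' @param labels Integer 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffles.
#' @return List of k elements, each `list(train = idx, test = idx)`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) < k || length(neg) < k) {
    stop(sprintf("each class needs >= k members (pos %d, neg %d, k %d)",
                 length(pos), length(neg), k), call. = FALSE)
  }
  set.seed(seed)
  pos <- sample(pos)
  neg <- sample(neg)
  pos_fold <- rep_len(seq_len(k), length(pos))
  neg_fold <- rep_len(seq_len(k), length(neg))
  lapply(seq_len(k), function(i) {
    test <- c(pos[pos_fold == i], neg[neg_fold == i])
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Train a comorbidity classifier
#'
#' Fits the configured SVM (via e1071) or random forest on a numeric
#' feature matrix and binary labels. Feature scaling is left to the caller
#' (see [cross_validate()], which standardizes on the training fold); the
#' SVM is fitted with `scale = FALSE`.
#'
#' @param x Numeric feature matrix (rows = disease pairs).
#' @param y Integer 0/1 labels.
#' @param cfg A [classifier_config()].
#' @return An object of class `comorb_model` exposing [predict_scores()].
#' @export
train_classifier <- function(x, y, cfg = classifier_config()) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("training labels contain a single class", call. = FALSE)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- switch(
    cfg$kind,
    svm_linear = e1071::svm(x, yf, kernel = "linear", cost = cfg$C,
                            scale = FALSE),
    svm_rbf = e1071::svm(x, yf, kernel = "radial", cost = cfg$C,
                         gamma = cfg$gamma, scale = FALSE),
    svm_poly = e1071::svm(x, yf, kernel = "polynomial", cost = cfg$C,
                          degree = cfg$degree, gamma = 1, coef0 = 1,
                          scale = FALSE),
    random_forest = {
      set.seed(cfg$seed)
      randomForest::randomForest(x, yf, ntree = cfg$n_trees)
    })
  structure(list(fit = fit, config = cfg), class = "comorb_model")
}

#' Continuous scores and hard labels from a trained model
#'
#' SVMs score by the signed decision-function margin (oriented so larger
#' means more likely comorbid); the random forest scores by the class-1
#' vote fraction. Hard labels use the model's default operating point.
#'
#' @param model A `comorb_model`.
#' @param newx Numeric feature matrix.
#' @return List with numeric `score` and integer `label` vectors.
#' @export
predict_scores <- function(model, newx) {
  newx <- as.matrix(newx)
  if (model$config$kind == "random_forest") {
    prob <- stats::predict(model$fit, newx, type = "prob")[, "1"]
    list(score = as.numeric(prob), label = as.integer(prob >= 0.5))
  } else {
    pred <- stats::predict(model$fit, newx, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # e1071 labels the column "A/B"; positive values favour class A
    favors <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1L]
    score <- if (identical(favors, "1")) dv[, 1L] else -dv[, 1L]
    list(score = as.numeric(score),
         label = as.integer(as.character(pred)))
  }
}

#' ROC AUC by the midrank statistic
#'
#' Probability that a uniformly random positive scores above a uniformly
#' random negative, with ties credited 0.5 (the Mann-Whitney U statistic
#' normalized by n1 * n0).
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param truth Integer 0/1 ground truth containing both classes.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, truth) {
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("ROC AUC needs both classes in truth", call. = FALSE)
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' True- and false-positive rates as the decision threshold sweeps down
#' the ranked scores.
#'
#' @param scores Numeric scores.
#' @param truth Integer 0/1 truth.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_points <- function(scores, truth) {
  ord <- order(scores, decreasing = TRUE)
  truth <- truth[ord]
  uniq_last <- !duplicated(scores[ord], fromLast = TRUE) # one point per distinct score
  tp <- cumsum(truth == 1L)[uniq_last]
  fp <- cumsum(truth == 0L)[uniq_last]
  data.frame(threshold = c(Inf, scores[ord][uniq_last]),
             fpr = c(0, fp / sum(truth == 0L)),
             tpr = c(0, tp / sum(truth == 1L)))
}

#' Evaluation metrics from scores, predictions and truth
#'
#' Counts the confusion matrix and computes recall = TP/(TP+FN),
#' precision = TP/(TP+FP), accuracy = (TP+TN)/total, F1 = 2PR/(P+R), and
#' ROC AUC from the continuous scores. If truth holds a single class, AUC
#' is NA with a warning and the remaining metrics are still returned.
#'
#' @param scores Numeric scores.
#' @param predicted Integer 0/1 hard predictions.
#' @param truth Integer 0/1 ground truth.
#' @return Named list of class `comorb_metrics`: `tp, tn, fp, fn,
#'   precision, recall, f1, accuracy, roc_auc`.
#' @export
evaluate_predictions <- function(scores, predicted, truth) {
  stopifnot(length(scores) == length(predicted),
            length(predicted) == length(truth))
  tp <- sum(predicted == 1L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  accuracy <- (tp + tn) / length(truth)
  auc <- if (length(unique(truth)) < 2L) {
    warning("truth contains a single class; ROC AUC undefined", call. = FALSE)
    NA_real_
  } else {
    roc_auc(scores, truth)
  }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, roc_auc = auc),
            class = "comorb_metrics")
}

#' @export
print.comorb_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f  ROC AUC %.3f\n",
              x$precision, x$recall, x$f1, x$accuracy, x$roc_auc))
  invisible(x)
}

#' Standardize features on training statistics
#'
#' Centers and unit-variance scales each feature column on the training
#' statistics, then divides by sqrt(n_features) so the expected squared
#' Euclidean distance between two training points is O(1) regardless of
#' the embedding dimension m. The fixed RBF width gamma is only
#' meaningful relative to a feature scale; this normalization keeps the
#' kernel non-degenerate for every configured m.
#'
#' @param train,test Numeric matrices.
#' @return List of standardized `train` and `test` matrices; columns with
#'   zero training variance are left centered only.
#' @keywords internal
standardize_on_train <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd) * sqrt(ncol(train))
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

#' Stratified k-fold cross-validation
#'
#' Runs the full supervised protocol: stratified splits, per-fold feature
#' standardization fitted on the training fold only, training, scoring the
#' held-out fold, and metric computation. Reports per-fold metrics and
#' their means.
#'
#' @param features Feature matrix from [build_feature_matrix()] (the pair
#'   identity and `rr` columns are ignored), or a plain numeric matrix.
#' @param labels Integer 0/1 labels aligned with rows.
#' @param cfg A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold shuffles.
#' @param standardize Standardize features per fold (default TRUE).
#' @return List of class `comorb_cv`: `folds` (data frame, one row per
#'   fold) and `summary` (named numeric means across folds).
#' @export
cross_validate <- function(features, labels, cfg = classifier_config(),
                           k = 10L, seed = 1L, standardize = TRUE) {
  x <- if (is.data.frame(features)) {
    as.matrix(features[, feature_columns(features), drop = FALSE])
  } else {
    as.matrix(features)
  }
  splits <- stratified_kfold(labels, k = k, seed = seed)
  fold_rows <- lapply(seq_along(splits), function(i) {
    tr <- splits[[i]]$train; te <- splits[[i]]$test
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    if (standardize) {
      std <- standardize_on_train(xtr, xte)
      xtr <- std$train; xte <- std$test
    }
    model <- train_classifier(xtr, labels[tr], cfg)
    pred <- predict_scores(model, xte)
    m <- evaluate_predictions(pred$score, pred$label, labels[te])
    data.frame(fold = i, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               accuracy = m$accuracy, roc_auc = m$roc_auc)
  })
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("precision", "recall", "f1", "accuracy", "roc_auc")
  structure(list(folds = folds,
                 summary = colMeans(folds[, metric_cols], na.rm = TRUE)),
            class = "comorb_cv")
}

#' @export
print.comorb_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation means:\n", nrow(x$folds)))
  print(round(x$summary, 4))
  invisible(x)
}

#' Paired significance test on per-fold metrics
#'
#' Two-sided paired t-test on per-fold metric values (typically ROC AUC)
#' of two methods evaluated on identical folds. Degenerate inputs are
#' handled explicitly: identical vectors give p = 1; a nonzero constant
#' difference (zero variance) gives p = 0.
#'
#' @param metrics_a,metrics_b Numeric vectors of equal length >= 2.
#' @return The two-sided p-value.
#' @export
paired_significance <- function(metrics_a, metrics_b) {
  if (length(metrics_a) != length(metrics_b)) {
    stop("per-fold metric vectors must have equal length", call. = FALSE)
  }
  if (length(metrics_a) < 2L) stop("need at least 2 folds", call. = FALSE)
  diffs <- metrics_a - metrics_b
  if (stats::sd(diffs) < .Machine$double.eps) {
    return(if (abs(mean(diffs)) < .Machine$double.eps) 1 else 0)
  }
  stats::t.test(metrics_a, metrics_b, paired = TRUE)$p.value
}
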