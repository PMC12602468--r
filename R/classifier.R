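# Disease-stage classification from flattened connectivity features.

#' Flatten per-subject connectivity matrices into a feature table
#'
#' Row-major flattening in the documented channel order: for target row i and
#' source column j the feature is named `"SRC->TGT"` (source first). With the
#' diagonal included a 7x7 matrix yields 49 features, without it 42.
#'
#' @param matrices List of [matrix_record()]s (one per subject, shared
#'   channels), kind `"tpdc"` or `"binary"` matching `mode`.
#' @param labels Stage label per subject (same order as `matrices`).
#' @param mode `"tpdc"` (continuous values, default) or `"binary"`.
#' @param include_diagonal Keep self-influence features? Default TRUE (49
#'   features for 7 channels).
#' @return An object of class `"feature_table"`: `features` (subjects x
#'   features numeric matrix), `labels` (factor), `channels`, `mode`.
#' @export
build_features <- function(matrices, labels, mode = c("tpdc", "binary"),
                           include_diagonal = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.list(matrices), length(matrices) >= 1,
            length(labels) == length(matrices))
  channels <- matrices[[1]]$channels
  N <- length(channels)
  keep <- if (include_diagonal) rep(TRUE, N * N) else as.vector(t(diag(N) == 0))
  nm <- as.vector(t(outer(seq_len(N), seq_len(N), function(i, j)
    paste0(channels[j], "->", channels[i]))))   # row-major: target outer
  feats <- matrix(0, length(matrices), sum(keep),
                  dimnames = list(NULL, nm[keep]))
  for (s in seq_along(matrices)) {
    m <- matrices[[s]]
    if (!inherits(m, "matrix_record") || !identical(m$channels, channels))
      stop(sprintf("subject %d: channel mismatch in feature construction", s),
           call. = FALSE)
    if (m$kind != mode)
      stop(sprintf("subject %d: matrix kind '%s' does not match mode '%s'",
                   s, m$kind, mode), call. = FALSE)
    feats[s, ] <- as.vector(t(m$values))[keep]
  }
  lab <- factor(labels)
  if (nlevels(lab) < 2) stop("at least 2 classes are required", call. = FALSE)
  structure(list(features = feats, labels = lab, channels = channels,
                 mode = mode, include_diagonal = include_diagonal),
            class = "feature_table")
}

# Stratified index split: returns test-set indices.
stratified_test_indices <- function(labels, test_fraction) {
  unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    n_test <- max(1, round(test_fraction * length(idx)))
    sample(idx, n_test)
  }), use.names = FALSE)
}

# Stratified k-fold assignment: fold id per subject.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Train and evaluate a random-forest stage classifier
#'
#' Stratified train/test split (default 70:30), a forest of `n_trees`
#' (default 100) fit on the training set, and held-out metrics: accuracy,
#' per-class precision/recall/F1, confusion matrix, normalized impurity
#' importances and (for two classes) the ROC curve and AUC from the
#' positive-class probability scores. Deterministic given `seed`.
#'
#' @param features A [build_features()] table (>= 10 subjects per class).
#' @param n_trees Number of trees.
#' @param test_fraction Held-out fraction per class.
#' @param seed RNG seed.
#' @param positive Positive class for the ROC (default: first factor level).
#' @return An object of class `"classifier_report"`.
#' @export
train_eval <- function(features, n_trees = 100, test_fraction = 0.30, seed = 1,
                       positive = levels(features$labels)[1]) {
  stopifnot(inherits(features, "feature_table"))
  counts <- table(features$labels)
  if (any(counts < 10))
    stop(sprintf("class '%s' has fewer than 10 subjects; stratified evaluation needs >= 10",
                 names(counts)[which.min(counts)]), call. = FALSE)
  lab <- features$labels
  X <- as.data.frame(features$features, check.names = FALSE)
  with_seed(seed, {
    test_idx <- sort(stratified_test_indices(lab, test_fraction))
    fit <- randomForest::randomForest(x = X[-test_idx, , drop = FALSE],
                                      y = lab[-test_idx], ntree = n_trees,
                                      importance = FALSE)
    pred <- predict(fit, X[test_idx, , drop = FALSE])
    prob <- predict(fit, X[test_idx, , drop = FALSE], type = "prob")
    truth <- lab[test_idx]
    cm <- table(truth = truth, predicted = pred)
    per_class <- lapply(levels(lab), function(cl) {
      tp <- sum(pred == cl & truth == cl)
      prec <- if (sum(pred == cl) > 0) tp / sum(pred == cl) else 0
      rec <- if (sum(truth == cl) > 0) tp / sum(truth == cl) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      list(class = cl, precision = prec, recall = rec, f1 = f1)
    })
    names(per_class) <- levels(lab)
    roc <- NULL; auc <- NA_real_
    if (nlevels(lab) == 2) {
      r <- pROC::roc(response = truth, predictor = prob[, positive],
                     levels = c(setdiff(levels(lab), positive), positive),
                     quiet = TRUE, direction = "<")
      roc <- data.frame(specificity = r$specificities,
                        sensitivity = r$sensitivities)
      auc <- as.numeric(r$auc)
    }
    imp <- randomForest::importance(fit, type = 2)[, 1]
    imp <- if (sum(imp) > 0) imp / sum(imp) else imp
    structure(list(accuracy = mean(pred == truth),
                   per_class = per_class,
                   confusion = cm,
                   roc = roc, auc = auc,
                   importance = sort(imp, decreasing = TRUE),
                   cv_mean = NA_real_, cv_sd = NA_real_,
                   n_trees = n_trees, test_fraction = test_fraction,
                   n_train = length(lab) - length(test_idx),
                   n_test = length(test_idx),
                   positive = positive, seed = seed,
                   model = fit),
              class = "classifier_report")
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.3f (train %d / test %d, %d trees)\n",
              x$accuracy, x$n_train, x$n_test, x$n_trees))
  for (pc in x$per_class)
    cat(sprintf("  %s: precision %.3f, recall %.3f, F1 %.3f\n",
                pc$class, pc$precision, pc$recall, pc$f1))
  if (!is.na(x$auc)) cat(sprintf("  ROC AUC: %.3f\n", x$auc))
  if (!is.na(x$cv_mean))
    cat(sprintf("  CV accuracy: %.3f +/- %.3f\n", x$cv_mean, x$cv_sd))
  invisible(x)
}

#' Stratified k-fold cross-validated accuracy
#'
#' @param features A [build_features()] table (>= `n_folds` subjects per
#'   class).
#' @param n_folds Number of folds (default 10).
#' @param n_trees Number of trees per fold.
#' @param seed RNG seed.
#' @return List with `cv_mean`, `cv_sd` and per-fold accuracies `folds`.
#' @export
cross_validate <- function(features, n_folds = 10, n_trees = 100, seed = 1) {
  stopifnot(inherits(features, "feature_table"))
  counts <- table(features$labels)
  if (any(counts < n_folds))
    stop(sprintf("class '%s' has fewer subjects than folds (%d < %d)",
                 names(counts)[which.min(counts)], min(counts), n_folds),
         call. = FALSE)
  lab <- features$labels
  X <- as.data.frame(features$features, check.names = FALSE)
  with_seed(seed, {
    fold <- stratified_folds(lab, n_folds)
    acc <- vapply(seq_len(n_folds), function(k) {
      fit <- randomForest::randomForest(x = X[fold != k, , drop = FALSE],
                                        y = lab[fold != k], ntree = n_trees)
      mean(predict(fit, X[fold == k, , drop = FALSE]) == lab[fold == k])
    }, numeric(1))
    list(cv_mean = mean(acc), cv_sd = sd(acc), folds = acc)
  })
}

#' Top-k most important connectivity features of a trained classifier
#'
#' Impurity-based (Gini) importances, normalized to sum to 1, in descending
#' order.
#'
#' @param report A [train_eval()] result.
#' @param k Number of features to report (default 5).
#' @return Data frame with columns `feature` and `importance`.
#' @export
rank_features <- function(report, k = 5) {
  stopifnot(inherits(report, "classifier_report"))
  imp <- report$importance
  k <- min(k, length(imp))
  data.frame(feature = names(imp)[seq_len(k)],
             importance = unname(imp[seq_len(k)]),
             stringsAsFactors = FALSE)
}
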