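#' Stratified train/test split
#'
#' Splits every class at the given ratio (default 50:50, the evaluation
#' protocol used throughout the pipeline), seeded.
#'
#' @param X numeric sample-by-feature matrix or `feature_matrix`.
#' @param y integer labels (taken from `X` when it carries them).
#' @param ratio train fraction in (0,1), default 0.5.
#' @param seed split seed.
#' @return list with `train` and `test`, each a list of `X` and `y`, plus
#'   the index vectors `train_idx` / `test_idx`.
#' @export
split_train_test <- function(X, y = NULL, ratio = 0.5, seed = 1L) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  if (is.null(y)) stop("labels required")
  tab <- table(y)
  if (min(tab) < 2L) stop("every class needs at least 2 samples")
  old <- .Random.seed_save()
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    n_tr <- round(length(idx) * ratio)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  .Random.seed_restore(old)
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx]),
       test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx]),
       train_idx = train_idx, test_idx = test_idx)
}

#' Supported classifier names
#'
#' MATLAB-style roster names mapped to open equivalents: quadratic/cubic SVM
#' are polynomial-kernel SVMs of degree 2/3, `fine_tree` a decision tree,
#' `gaussian_nb` naive Bayes, `weighted_knn` a distance-weighted 10-NN,
#' `cubic_knn` a Minkowski p=3 10-NN, and narrow/medium/wide NN are
#' single-hidden-layer feed-forward nets of size 10/25/100.
#'
#' @return character vector of names accepted by [evaluate_classifier()].
#' @export
supported_classifiers <- function() {
  c("quadratic_svm", "cubic_svm", "fine_tree", "gaussian_nb",
    "weighted_knn", "cubic_knn", "narrow_nn", "medium_nn", "wide_nn")
}

#' Fit a named classifier and evaluate it on a held-out test set
#'
#' @param train,test lists with fields `X` (matrix) and `y` (integer labels),
#'   as produced by [split_train_test()].
#' @param classifier one of [supported_classifiers()].
#' @param seed seed (nets have random starting weights).
#' @return an `eval_report`: confusion matrix (rows = true class), accuracy,
#'   macro recall/precision/F1, FNR (100 - macro recall), per-class table,
#'   elapsed seconds. All metrics are percentages.
#' @export
evaluate_classifier <- function(train, test, classifier = "cubic_svm",
                                seed = 1L) {
  if (!classifier %in% supported_classifiers())
    stop("unknown classifier '", classifier, "'; supported: ",
         paste(supported_classifiers(), collapse = ", "))
  t0 <- proc.time()["elapsed"]
  ytr <- factor(train$y)
  Xtr <- as.matrix(train$X); Xte <- as.matrix(test$X)
  old <- .Random.seed_save()
  set.seed(seed)
  pred <- switch(classifier,
    quadratic_svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "polynomial", degree = 2,
                        coef0 = 1, scale = FALSE)
      stats::predict(fit, Xte)
    },
    cubic_svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "polynomial", degree = 3,
                        coef0 = 1, scale = FALSE)
      stats::predict(fit, Xte)
    },
    fine_tree = {
      df <- data.frame(y = ytr, Xtr)
      fit <- rpart::rpart(y ~ ., df,
                          control = rpart::rpart.control(cp = 1e-4,
                                                         minsplit = 4))
      stats::predict(fit, data.frame(Xte), type = "class")
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      stats::predict(fit, Xte)
    },
    weighted_knn = factor(knn_predict(Xtr, as.integer(as.character(ytr)),
                                      Xte, k = 10L, weighted = TRUE),
                          levels = levels(ytr)),
    cubic_knn = factor(knn_predict(Xtr, as.integer(as.character(ytr)),
                                   Xte, k = 10L, p = 3),
                       levels = levels(ytr)),
    narrow_nn = nn_predict(Xtr, ytr, Xte, size = 10L),
    medium_nn = nn_predict(Xtr, ytr, Xte, size = 25L),
    wide_nn = nn_predict(Xtr, ytr, Xte, size = 100L))
  .Random.seed_restore(old)
  elapsed <- proc.time()["elapsed"] - t0
  report_metrics(true = factor(test$y, levels = levels(ytr)),
                 pred = factor(pred, levels = levels(ytr)),
                 elapsed = unname(elapsed))
}

nn_predict <- function(Xtr, ytr, Xte, size) {
  capture <- utils::capture.output(
    fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = size,
                      softmax = TRUE, maxit = 200, MaxNWts = 100000,
                      trace = FALSE))
  lev <- levels(ytr)
  factor(lev[max.col(stats::predict(fit, Xte))], levels = lev)
}

#' Classification report from true and predicted labels
#'
#' @param true,pred factors over the same levels.
#' @param elapsed wall-clock seconds to include in the report.
#' @return an `eval_report` list: `confusion` (C x C, rows = true),
#'   `accuracy`, `macro_recall`, `macro_precision`, `macro_f1`, `fnr`
#'   (all percentages), `per_class` data frame, `elapsed_seconds`.
#' @export
report_metrics <- function(true, pred, elapsed = NA_real_) {
  conf <- table(true = true, pred = pred)
  conf <- unclass(conf)
  n <- sum(conf)
  tp <- diag(conf)
  recall <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  precision <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  macro_recall <- mean(recall) * 100
  macro_precision <- mean(precision) * 100
  structure(list(
    confusion = conf,
    accuracy = sum(tp) / n * 100,
    macro_recall = macro_recall,
    macro_precision = macro_precision,
    macro_f1 = mean(f1) * 100,
    fnr = 100 - macro_recall,
    per_class = data.frame(class = rownames(conf),
                           n = rowSums(conf),
                           recall = recall * 100,
                           precision = precision * 100,
                           f1 = f1 * 100,
                           row.names = NULL),
    elapsed_seconds = elapsed), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 1, ...) {
  cat("Classification report\n")
  cat(sprintf("  accuracy: %.*f%%  macro recall: %.*f%%  macro precision: %.*f%%\n",
              digits, x$accuracy, digits, x$macro_recall,
              digits, x$macro_precision))
  cat(sprintf("  macro F1: %.*f%%  FNR: %.*f%%\n",
              digits, x$macro_f1, digits, x$fnr))
  if (is.finite(x$elapsed_seconds))
    cat(sprintf("  elapsed: %.2fs\n", x$elapsed_seconds))
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
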