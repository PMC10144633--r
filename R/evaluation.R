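# Evaluation harness: confusion matrices, accuracy, stratified k-fold
# cross-validation of the fusion pipeline, and the baseline classifier
# comparison (kNN, random tree, random forest, SVM, MLP).

#' 2x2 confusion matrix with fatigued as the positive class
#'
#' @param predicted,actual equal-length label vectors with values
#'   `"alert"`/`"fatigued"`.
#' @return a `confusion_matrix`: named vector (TP, FN, FP, TN).
#' @export
confusion_matrix <- function(predicted, actual) {
  if (length(predicted) != length(actual) || length(actual) == 0L)
    stop_invalid("predicted and actual must have equal positive length")
  if (!all(c(predicted, actual) %in% c("alert", "fatigued")))
    stop_invalid("labels must be 'alert' or 'fatigued'")
  structure(c(TP = sum(predicted == "fatigued" & actual == "fatigued"),
              FN = sum(predicted == "alert" & actual == "fatigued"),
              FP = sum(predicted == "fatigued" & actual == "alert"),
              TN = sum(predicted == "alert" & actual == "alert")),
            class = "confusion_matrix")
}

#' Classification accuracy in percent
#'
#' `100 (TP + TN) / (TP + FN + FP + TN)`.
#'
#' @param cm a [confusion_matrix()] or a length-4 vector
#'   (TP, FN, FP, TN).
#' @return accuracy in percent.
#' @export
accuracy <- function(cm) {
  cm <- as.numeric(cm)
  if (length(cm) != 4L || any(cm < 0))
    stop_invalid("cm must hold four non-negative counts")
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  100 * (cm[1] + cm[4]) / total
}

#' Seeded stratified fold assignment
#'
#' Shuffles within each class and deals members to folds round-robin,
#' so folds partition the cohort exactly once and every fold is as
#' balanced as the class sizes allow.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per subject.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  if (min(table(labels)) < k)
    stop_invalid("need at least k = ", k, " records per class")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the fusion pipeline
#'
#' For each fold, domain scorers and fusion weights are fitted on the
#' training records only and evaluated on the held-out fold; no test
#' subject influences its own model.
#'
#' @param records labelled `subject_record`s (>= k per class).
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @param corr_cap,resolution,threshold fusion-model parameters, see
#'   [fit_fusion_model()].
#' @return a `fold_report`: list with per-fold `confusions` and
#'   `accuracies` (percent) and their arithmetic `average`.
#' @export
kfold_cv <- function(records, k = 3, seed = 1, corr_cap = 0.9,
                     resolution = 0.01, threshold = 0.5) {
  labels <- record_labels(records)
  fold <- stratified_folds(labels, k, seed)
  confusions <- list()
  accuracies <- numeric(k)
  for (f in seq_len(k)) {
    train <- records[fold != f]
    test <- records[fold == f]
    if (length(unique(record_labels(train))) < 2L)
      stop_invalid("a class is absent from fold ", f, "'s training set")
    model <- fit_fusion_model(train, corr_cap = corr_cap,
                              resolution = resolution,
                              threshold = threshold)
    pred <- predict_fatigue(model, test)
    cm <- confusion_matrix(pred$predicted, record_labels(test))
    confusions[[f]] <- cm
    accuracies[f] <- accuracy(cm)
  }
  structure(list(confusions = confusions,
                 accuracies = accuracies,
                 average = mean(accuracies),
                 fold = fold),
            class = "fold_report")
}

#' @export
print.fold_report <- function(x, ...) {
  cat("Stratified", length(x$accuracies), "fold cross-validation\n")
  for (f in seq_along(x$accuracies)) {
    cm <- x$confusions[[f]]
    cat(sprintf("  fold %d: TP=%d FN=%d FP=%d TN=%d  accuracy %.2f%%\n",
                f, cm["TP"], cm["FN"], cm["FP"], cm["TN"],
                x$accuracies[f]))
  }
  cat(sprintf("  average accuracy %.2f%%\n", x$average))
  invisible(x)
}

BASELINE_CLASSIFIERS <- c("knn", "random_tree", "random_forest", "svm",
                          "mlp")

# z-score a test matrix by training statistics; zero-variance columns
# are dropped.
standardize_split <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sd <- apply(train_x, 2, stats::sd)
  keep <- sd > 0
  list(train = scale(train_x[, keep, drop = FALSE], mu[keep], sd[keep]),
       test = scale(test_x[, keep, drop = FALSE], mu[keep], sd[keep]))
}

fit_predict_baseline <- function(name, train_x, train_y, test_x, seed) {
  set.seed(seed)
  train_y <- factor(train_y, levels = c("alert", "fatigued"))
  switch(name,
    knn = as.character(class::knn(train_x, test_x, train_y, k = 5)),
    random_tree = {
      df <- data.frame(train_x, y = train_y, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df, method = "class")
      as.character(predict(fit, data.frame(test_x, check.names = FALSE),
                           type = "class"))
    },
    random_forest = {
      fit <- randomForest::randomForest(train_x, train_y, ntree = 100)
      as.character(predict(fit, test_x))
    },
    svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "radial")
      as.character(predict(fit, test_x))
    },
    mlp = {
      df <- data.frame(train_x, check.names = FALSE)
      df$y <- train_y
      fit <- nnet::nnet(y ~ ., data = df, size = 16, maxit = 300,
                        decay = 1e-4, trace = FALSE)
      as.character(predict(fit, data.frame(test_x, check.names = FALSE),
                           type = "class"))
    },
    stop_invalid("unknown classifier: ", name))
}

#' Baseline classifier comparison on a holdout split
#'
#' Trains the five named baselines (kNN with k = 5, a single decision
#' tree, a 100-tree random forest, a radial-kernel SVM, and a
#' one-hidden-layer-of-16 perceptron) on the same stratified split of a
#' feature matrix and reports test accuracy and correct/incorrect
#' counts.  Features are z-scored by training statistics.  When
#' `records` are supplied instead of a matrix, the 20-feature
#' concatenation of all four domains is used, and a `fusion` row
#' evaluating the full score-fusion pipeline on the same split can be
#' appended.
#'
#' @param records labelled `subject_record`s, or `NULL` when
#'   `feature_matrix`/`labels` are given directly.
#' @param feature_matrix subjects x features matrix (ignored when
#'   `records` is given).
#' @param labels label vector matching `feature_matrix`.
#' @param train_frac fraction of each class used for training (the
#'   published protocol trains on 2/3: 80 of 120).
#' @param seed split/classifier seed.
#' @param classifiers subset of
#'   `c("knn", "random_tree", "random_forest", "svm", "mlp")`.
#' @param include_fusion also evaluate the fusion pipeline on the same
#'   split (requires `records`).
#' @return data.frame (classifier, accuracy, correct, incorrect, n_test).
#' @export
baseline_comparison <- function(records = NULL, feature_matrix = NULL,
                                labels = NULL, train_frac = 2 / 3,
                                seed = 1,
                                classifiers = BASELINE_CLASSIFIERS,
                                include_fusion = !is.null(records)) {
  if (!is.null(records)) {
    labels <- record_labels(records)
    feature_matrix <- do.call(cbind, lapply(DOMAINS, function(d)
      domain_matrix(records, d)))
  }
  if (is.null(feature_matrix) || is.null(labels))
    stop_invalid("supply records, or feature_matrix plus labels")
  bad <- !classifiers %in% BASELINE_CLASSIFIERS
  if (any(bad))
    stop_invalid("unknown classifier: ", classifiers[bad][1])
  if (min(table(labels)) < 2L)
    stop_invalid("need >= 2 subjects per class")
  set.seed(seed)
  train_idx <- unlist(lapply(unique(labels), function(cl) {
    idx <- sample(which(labels == cl))
    idx[seq_len(round(train_frac * length(idx)))]
  }))
  test_idx <- setdiff(seq_along(labels), train_idx)
  std <- standardize_split(feature_matrix[train_idx, , drop = FALSE],
                           feature_matrix[test_idx, , drop = FALSE])
  rows <- lapply(classifiers, function(nm) {
    pred <- fit_predict_baseline(nm, std$train, labels[train_idx],
                                 std$test, seed)
    correct <- sum(pred == labels[test_idx])
    data.frame(classifier = nm,
               accuracy = 100 * correct / length(test_idx),
               correct = correct,
               incorrect = length(test_idx) - correct,
               n_test = length(test_idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_fusion) {
    model <- fit_fusion_model(records[train_idx])
    pred <- predict_fatigue(model, records[test_idx])
    correct <- sum(pred$predicted == labels[test_idx])
    out <- rbind(out, data.frame(
      classifier = "fusion",
      accuracy = 100 * correct / length(test_idx),
      correct = correct,
      incorrect = length(test_idx) - correct,
      n_test = length(test_idx),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
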