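# Repeated random-subsampling cross-validation over SVM / random-forest
# back-ends, confusion matrices and the colors-vs-accuracy experiment.

#' Cross-validation configuration
#'
#' Defaults follow the study design: 100 repetitions of an unstratified
#' random 80/20 train/test split; random forest with 14 candidate variables
#' per split and 500 trees; SVM with an RBF kernel.
#'
#' @param classifier \code{"svm"} or \code{"rf"}.
#' @param n_reps number of random train/test repetitions.
#' @param test_fraction held-out fraction per repetition (test size is
#'   \code{floor(test_fraction * n)}).
#' @param seed root seed; each repetition derives its own stream from it.
#' @param svm_kernel,svm_cost,svm_gamma SVM parameters (\code{svm_gamma =
#'   NULL} uses 1/p).
#' @param svm_tune run a small LIBSVM-style grid search over (cost, gamma)
#'   on the training split (off by default; multiplies cost).
#' @param rf_mtry,rf_ntree random-forest parameters (\code{mtry} is capped
#'   at p).
#' @param scale_range min-max scaling range fitted per split on the training
#'   rows only.
#' @param select_threshold if non-\code{NULL}, per-repetition F-score
#'   selection at this threshold, fitted on the training split.
#' @return A \code{cv_config} list.
#' @export
cv_config <- function(classifier = c("svm", "rf"),
                      n_reps = 100L, test_fraction = 0.2, seed = 1L,
                      svm_kernel = "radial", svm_cost = 10, svm_gamma = NULL,
                      svm_tune = FALSE,
                      rf_mtry = 14L, rf_ntree = 500L,
                      scale_range = c(0, 1), select_threshold = NULL) {
  classifier <- match.arg(classifier)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie in (0, 1)")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  structure(list(classifier = classifier, n_reps = as.integer(n_reps),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 svm_kernel = svm_kernel, svm_cost = svm_cost,
                 svm_gamma = svm_gamma, svm_tune = svm_tune,
                 rf_mtry = as.integer(rf_mtry), rf_ntree = as.integer(rf_ntree),
                 scale_range = scale_range,
                 select_threshold = select_threshold),
            class = "cv_config")
}

#' Train a classifier on a labeled feature table
#'
#' Thin dispatch over the established back-ends: \code{e1071::svm} (RBF by
#' default) and \code{randomForest::randomForest} (\code{mtry} capped at the
#' number of features). RF training is seeded, so identical data and seed
#' give identical forests.
#'
#' @param train a \code{\link{labeled_feature_table}} with >= 2 classes.
#' @param config a \code{\link{cv_config}}.
#' @param seed seed for the (stochastic) RF back-end.
#' @return Object of class \code{fin_classifier} with a
#'   \code{\link{predict.fin_classifier}} method.
#' @export
train_classifier <- function(train, config = cv_config(), seed = config$seed) {
  stopifnot(inherits(train, "labeled_feature_table"))
  if (nlevels(droplevels(train$y)) < 2L)
    stop("training set must contain at least 2 classes")
  X <- train$X
  keep_cols <- colnames(X)
  if (config$classifier == "svm") {
    gamma <- if (is.null(config$svm_gamma)) 1 / ncol(X) else config$svm_gamma
    cost <- config$svm_cost
    if (isTRUE(config$svm_tune)) {
      set.seed(seed)
      tuned <- e1071::tune.svm(X, train$y, kernel = config$svm_kernel,
                               cost = 4^(-1:3), gamma = gamma * 4^(-2:2))
      cost <- tuned$best.parameters$cost
      gamma <- tuned$best.parameters$gamma
    }
    fit <- e1071::svm(X, train$y, kernel = config$svm_kernel,
                      cost = cost, gamma = gamma, scale = FALSE)
  } else {
    set.seed(seed)
    fit <- randomForest::randomForest(
      X, train$y, mtry = min(config$rf_mtry, ncol(X)),
      ntree = config$rf_ntree)
  }
  structure(list(fit = fit, classifier = config$classifier,
                 features = keep_cols, levels = levels(train$y)),
            class = "fin_classifier")
}

#' Predict class labels
#'
#' @param object a \code{\link{train_classifier}} result.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.fin_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  stats::predict(object$fit, newdata)
}

#' Variable importance of a random-forest classifier
#'
#' @param object a \code{\link{train_classifier}} result with
#'   \code{classifier = "rf"}.
#' @return Data frame of mean-decrease-in-Gini importance, descending.
#' @export
rf_importance <- function(object) {
  stopifnot(inherits(object, "fin_classifier"))
  if (object$classifier != "rf") stop("importance is defined for rf only")
  imp <- randomForest::importance(object$fit)
  data.frame(variable = rownames(imp),
             MeanDecreaseGini = imp[, "MeanDecreaseGini"],
             row.names = NULL)[order(-imp[, "MeanDecreaseGini"]), ]
}

#' Repeated random-subsampling cross-validation
#'
#' Each repetition draws a uniform (unstratified) random partition holding
#' out \code{floor(test_fraction * n)} rows, fits min-max scaling (and,
#' optionally, F-score selection) on the training rows only, trains the
#' classifier and predicts the held-out rows. Repetitions whose training
#' split lacks a class are redrawn (and counted). With n = 594, 100
#' repetitions and a 20\% test split this pools 11,800 predictions.
#'
#' @param table a \code{\link{labeled_feature_table}} (n >= 10).
#' @param config a \code{\link{cv_config}}.
#' @return Object of class \code{fin_cv}: \code{predictions} (data frame
#'   with \code{rep}, \code{id}, \code{actual}, \code{predicted}),
#'   \code{accuracy_mean}, \code{accuracy_sd}, per-repetition
#'   \code{accuracies}, \code{redraws} and the \code{config}.
#' @export
repeated_holdout_cv <- function(table, config = cv_config()) {
  stopifnot(inherits(table, "labeled_feature_table"))
  n <- nrow(table$X)
  if (n < 10L) stop("need at least 10 specimens")
  n_test <- floor(config$test_fraction * n)
  if (n_test < 1L) stop("test split is empty")
  ids <- rownames(table$X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  accs <- numeric(config$n_reps)
  preds <- vector("list", config$n_reps)
  redraws <- 0L
  for (rep in seq_len(config$n_reps)) {
    set.seed((config$seed * 2003L + rep) %% .Machine$integer.max)
    repeat {
      test_idx <- sample.int(n, n_test)
      y_train <- droplevels(table$y[-test_idx])
      if (nlevels(y_train) == nlevels(droplevels(table$y))) break
      redraws <- redraws + 1L
    }
    train <- labeled_feature_table(table$X[-test_idx, , drop = FALSE],
                                   table$y[-test_idx])
    test <- labeled_feature_table(table$X[test_idx, , drop = FALSE],
                                  table$y[test_idx])
    if (!is.null(config$select_threshold)) {
      keep <- select_features(train, threshold = config$select_threshold)
      if (length(keep) > 0L) {
        train <- labeled_feature_table(train$X[, keep, drop = FALSE], train$y)
        test <- labeled_feature_table(test$X[, keep, drop = FALSE], test$y)
      }
    }
    sc <- suppressWarnings(
      scale_features(train, test, range = config$scale_range))
    clf <- train_classifier(sc$train, config,
                            seed = (config$seed * 7001L + rep) %%
                                   .Machine$integer.max)
    p <- predict(clf, sc$apply_to$X)
    accs[rep] <- mean(as.character(p) == as.character(test$y))
    preds[[rep]] <- data.frame(rep = rep, id = ids[test_idx],
                               actual = as.character(test$y),
                               predicted = as.character(p),
                               stringsAsFactors = FALSE)
  }
  structure(list(predictions = do.call(rbind, preds),
                 accuracy_mean = 100 * mean(accs),
                 accuracy_sd = 100 * stats::sd(accs),
                 accuracies = 100 * accs,
                 redraws = redraws,
                 levels = levels(table$y),
                 config = config),
            class = "fin_cv")
}

#' @export
print.fin_cv <- function(x, ...) {
  cat(sprintf(
    "<fin_cv> %s, %d reps x %.0f%% test: accuracy %.1f%% (s.d. %.1f), %d pooled predictions\n",
    toupper(x$config$classifier), x$config$n_reps,
    100 * x$config$test_fraction, x$accuracy_mean, x$accuracy_sd,
    nrow(x$predictions)))
  invisible(x)
}

#' @export
summary.fin_cv <- function(object, ...) {
  cm <- confusion_matrix(object$predictions, levels = object$levels)
  cat(sprintf("Repeated holdout CV (%s): mean accuracy %.2f%% (s.d. %.2f%%)\n",
              toupper(object$config$classifier),
              object$accuracy_mean, object$accuracy_sd))
  print(cm)
  invisible(cm)
}

#' Confusion matrix of pooled predictions
#'
#' Counts with predicted class in rows and actual class in columns, so entry
#' (p, a) is the number of times class a was predicted as p; column sums,
#' per-class accuracy (diagonal / column sum, %) and overall accuracy
#' (trace / total, %) are attached.
#'
#' @param predictions data frame with \code{actual} and \code{predicted}
#'   columns (as from \code{\link{repeated_holdout_cv}}).
#' @param levels class set; defaults to the labels present.
#' @return Object of class \code{fin_confusion}: \code{counts} matrix,
#'   \code{sums}, \code{class_accuracy} (%), \code{overall_accuracy} (%).
#' @export
confusion_matrix <- function(predictions, levels = NULL) {
  if (is.null(predictions) || nrow(predictions) == 0L)
    stop("no predictions")
  if (is.null(levels))
    levels <- sort(unique(c(predictions$actual, predictions$predicted)))
  bad <- setdiff(unique(c(predictions$actual, predictions$predicted)), levels)
  if (length(bad) > 0L)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(predictions$predicted, levels = levels),
                  factor(predictions$actual, levels = levels))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("predicted", "actual")
  sums <- colSums(counts)
  class_acc <- ifelse(sums > 0, 100 * diag(counts) / sums, NA_real_)
  structure(list(counts = counts, sums = sums,
                 class_accuracy = class_acc,
                 overall_accuracy = 100 * sum(diag(counts)) / sum(counts)),
            class = "fin_confusion")
}

#' @export
print.fin_confusion <- function(x, digits = 2, ...) {
  m <- rbind(x$counts, Sum = x$sums,
             `Accuracy(%)` = round(x$class_accuracy, digits))
  print(m)
  cat(sprintf("Overall accuracy: %.2f%% (%d predictions)\n",
              x$overall_accuracy, sum(x$counts)))
  invisible(x)
}

#' Classifier accuracy versus number of palette colors
#'
#' For k = 1..\code{max_colors}, runs cross-validation using only the 6k
#' features of the k most frequent quantized colors (no other features), to
#' show how much of the discriminative signal each additional palette color
#' adds.
#'
#' @param table a \code{\link{labeled_feature_table}} containing the 42
#'   \code{Color_<j>_<c>} columns.
#' @param config a \code{\link{cv_config}}.
#' @param max_colors largest palette prefix to evaluate (<= 7).
#' @return Data frame with \code{n_colors}, \code{accuracy_mean},
#'   \code{accuracy_sd}.
#' @export
colors_vs_accuracy <- function(table, config = cv_config(), max_colors = 7L) {
  stopifnot(inherits(table, "labeled_feature_table"))
  out <- data.frame(n_colors = seq_len(max_colors),
                    accuracy_mean = NA_real_, accuracy_sd = NA_real_)
  for (k in seq_len(max_colors)) {
    cols <- as.vector(t(outer(paste0("Color_", seq_len(k) - 1, "_"),
                              c("r", "g", "b", "h", "s", "v"), paste0)))
    if (!all(cols %in% colnames(table$X)))
      stop("table lacks the color feature columns")
    sub <- labeled_feature_table(table$X[, cols, drop = FALSE], table$y)
    cv <- repeated_holdout_cv(sub, config)
    out$accuracy_mean[k] <- cv$accuracy_mean
    out$accuracy_sd[k] <- cv$accuracy_sd
  }
  out
}
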