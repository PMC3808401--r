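make_sep_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n / 2)
  X <- cbind(f1 = rnorm(n, ifelse(y == "A", 0, 5)),
             f2 = rnorm(n, ifelse(y == "A", 5, 0)))
  rownames(X) <- sprintf("s%02d", seq_len(n))
  labeled_feature_table(X, y)
}

test_that("classifiers fit separable data perfectly and deterministically", {
  tab <- make_sep_table()
  for (clf in c("svm", "rf")) {
    fit <- train_classifier(tab, cv_config(clf, seed = 3))
    expect_equal(mean(as.character(predict(fit, tab$X)) ==
                      as.character(tab$y)), 1)
  }
  f1 <- train_classifier(tab, cv_config("rf", seed = 9), seed = 9)
  f2 <- train_classifier(tab, cv_config("rf", seed = 9), seed = 9)
  expect_identical(as.character(predict(f1, tab$X)),
                   as.character(predict(f2, tab$X)))
  one_class <- labeled_feature_table(tab$X, rep("A", nrow(tab$X)))
  expect_error(train_classifier(one_class, cv_config("svm")), "2 classes")
})

test_that("RF importance ranks a fully class-determining feature first", {
  set.seed(41)
  n <- 80
  y <- rep(c("A", "B"), each = n / 2)
  X <- cbind(signal = ifelse(y == "A", 0, 1) + rnorm(n, 0, 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  fit <- train_classifier(labeled_feature_table(X, y),
                          cv_config("rf", rf_mtry = 2), seed = 4)
  expect_identical(rf_importance(fit)$variable[1], "signal")
})

test_that("repeated holdout pools floor(test_fraction * n) predictions per rep", {
  tab <- make_sep_table(n = 10)
  cv <- repeated_holdout_cv(tab, cv_config("svm", n_reps = 1, seed = 2))
  expect_equal(nrow(cv$predictions), 2)  # floor(0.2 * 10)
  cv3 <- repeated_holdout_cv(tab, cv_config("svm", n_reps = 3, seed = 2))
  expect_equal(nrow(cv3$predictions), 6)
  expect_error(repeated_holdout_cv(make_sep_table(8), cv_config("svm")),
               "at least 10")
})

test_that("cross-validation is reproducible under a fixed seed", {
  tab <- make_sep_table(n = 40, seed = 5)
  a <- repeated_holdout_cv(tab, cv_config("rf", n_reps = 4, seed = 12))
  b <- repeated_holdout_cv(tab, cv_config("rf", n_reps = 4, seed = 12))
  expect_identical(a$predictions, b$predictions)
  expect_equal(a$accuracy_mean, b$accuracy_mean)
})

test_that("training splits missing a class are redrawn", {
  set.seed(8)
  y <- c(rep("A", 3), rep("B", 37))  # rare class often fully held out
  X <- cbind(f1 = rnorm(40, ifelse(y == "A", 0, 5)), f2 = rnorm(40))
  tab <- labeled_feature_table(X, y)
  cv <- repeated_holdout_cv(tab, cv_config("svm", n_reps = 50,
                                           test_fraction = 0.5, seed = 1))
  expect_gt(cv$redraws, 0)
  # every repetition still trained on both classes: all predictions defined
  expect_false(anyNA(cv$predictions$predicted))
})

test_that("confusion matrices satisfy their conservation laws", {
  preds <- data.frame(
    actual = c(rep("A", 50), rep("B", 30)),
    predicted = c(rep("A", 45), rep("B", 5), rep("B", 27), rep("A", 3)))
  cm <- confusion_matrix(preds)
  expect_equal(sum(cm$counts), 80)
  expect_equal(unname(cm$sums), c(50, 30))
  expect_equal(unname(cm$class_accuracy), c(90, 90))
  expect_equal(cm$overall_accuracy, 100 * 72 / 80)
  expect_equal(cm$counts["B", "A"], 5)  # A mistaken for B five times
  # per-class accuracy at the printed precision: 128 of 191 -> 67.02
  preds2 <- data.frame(actual = rep("gm_f", 191),
                       predicted = c(rep("gm_f", 128), rep("pe_m", 63)))
  cm2 <- confusion_matrix(preds2, levels = c("gm_f", "pe_m"))
  expect_equal(round(cm2$class_accuracy[["gm_f"]], 2), 67.02)
  expect_error(confusion_matrix(preds[0, ]), "no predictions")
  expect_error(confusion_matrix(preds, levels = "A"), "unknown label")
})

test_that("perfect predictions give a diagonal confusion matrix", {
  preds <- data.frame(actual = rep(letters[1:3], 5),
                      predicted = rep(letters[1:3], 5))
  cm <- confusion_matrix(preds)
  expect_true(all(cm$counts[upper.tri(cm$counts)] == 0))
  expect_true(all(cm$counts[lower.tri(cm$counts)] == 0))
  expect_equal(cm$overall_accuracy, 100)
})

test_that("conservation holds on pooled CV output at fixed seed", {
  dj <- disjoint_fixture()
  cv <- repeated_holdout_cv(dj$table, cv_config("svm", n_reps = 5, seed = 3))
  cm <- confusion_matrix(cv$predictions, levels = cv$levels)
  expect_equal(sum(cm$counts), 5 * floor(0.2 * nrow(dj$table$X)))
  expect_equal(unname(colSums(cm$counts)), unname(cm$sums))
  expect_equal(cm$overall_accuracy,
               100 * sum(diag(cm$counts)) / sum(cm$counts))
})

test_that("accuracy is not driven by class sample size on synthetic data", {
  ov <- overlap_fixture()
  # unbalanced subsample: class sizes 7..12, unrelated to pair difficulty
  set.seed(19)
  sizes <- c(7, 12, 8, 11, 9, 12)
  idx <- unlist(lapply(seq_along(sizes), function(i)
    sample(which(ov$ds$labels == sort(unique(ov$ds$labels))[i]), sizes[i])))
  tab <- labeled_feature_table(ov$table48$X[idx, ], ov$ds$labels[idx])
  cv <- repeated_holdout_cv(tab, cv_config("svm", n_reps = 20, seed = 23))
  cm <- confusion_matrix(cv$predictions, levels = cv$levels)
  ct <- suppressWarnings(
    cor.test(table(tab$y)[names(cm$class_accuracy)], cm$class_accuracy,
             method = "spearman"))
  expect_gt(ct$p.value, 0.01)
})

test_that("colors-vs-accuracy uses exactly the k most frequent colors", {
  specs <- list(
    class_spec("c1", list(list(rgb = c(200, 40, 40), prop = 0.6),
                          list(rgb = c(40, 40, 200), prop = 0.4)),
               color_noise_sd = 5),
    class_spec("c2", list(list(rgb = c(40, 200, 40), prop = 0.6),
                          list(rgb = c(200, 200, 40), prop = 0.4)),
               color_noise_sd = 5),
    class_spec("c3", list(list(rgb = c(40, 200, 200), prop = 0.6),
                          list(rgb = c(200, 40, 200), prop = 0.4)),
               color_noise_sd = 5))
  ds <- generate_dataset(specs, n_per_class = 8, seed = 31)
  feats <- extract_feature_table(ds$images, ids = ds$ids)
  tab <- labeled_feature_table(feats, ds$labels)
  res <- colors_vs_accuracy(tab, cv_config("svm", n_reps = 5, seed = 7),
                            max_colors = 3)
  # disjoint first colors: the dominant color alone separates the classes
  expect_gte(res$accuracy_mean[1], 95)
  # k = max equals a CV run on the full color block
  cols <- grep("^Color_", colnames(feats), value = TRUE)
  full <- repeated_holdout_cv(
    labeled_feature_table(feats[, cols], ds$labels),
    cv_config("svm", n_reps = 5, seed = 7))
  expect_equal(res$accuracy_mean[3], full$accuracy_mean)
  expect_error(colors_vs_accuracy(
    labeled_feature_table(feats[, 43:48], ds$labels),
    cv_config("svm", n_reps = 2, seed = 1), max_colors = 2),
    "color feature")
})

test_that("classes separable only by the second color need k >= 2", {
  # noise-free so the shared dominant color is quantized identically in
  # every class and carries no class signal
  shared <- list(rgb = c(150, 150, 150), prop = 0.6)
  specs <- list(
    class_spec("d1", list(shared, list(rgb = c(200, 30, 30), prop = 0.4)),
               color_noise_sd = 0),
    class_spec("d2", list(shared, list(rgb = c(30, 30, 200), prop = 0.4)),
               color_noise_sd = 0),
    class_spec("d3", list(shared, list(rgb = c(220, 220, 30), prop = 0.4)),
               color_noise_sd = 0))
  ds <- generate_dataset(specs, n_per_class = 8, seed = 37)
  feats <- extract_feature_table(ds$images, ids = ds$ids)
  tab <- labeled_feature_table(feats, ds$labels)
  res <- colors_vs_accuracy(tab, cv_config("svm", n_reps = 5, seed = 7),
                            max_colors = 2)
  expect_gte(res$accuracy_mean[2] - res$accuracy_mean[1], 20)
})
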