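# End-to-end orchestration: simulate/mask -> extract -> gpa -> select -> cv
# (-> mantel), with a deterministic report bundle.

#' Pipeline configuration
#'
#' Everything the end-to-end run needs: the extractor parameters, the
#' F-score selection threshold, the scaling range, the CV setup and the
#' stage toggles. All randomness flows from the single root \code{seed},
#' split deterministically per stage.
#'
#' @param seed root seed.
#' @param extractor an \code{\link{extractor_config}}.
#' @param use_gm append the 34 Procrustes shape coordinates (default
#'   \code{TRUE}).
#' @param use_selection apply F-score selection at
#'   \code{select_threshold} once, globally, before CV (default
#'   \code{FALSE}, matching a selection study done as a separate step).
#' @param select_threshold F-score threshold (default 0.7).
#' @param normalize_colors per-image channel stretching before extraction;
#'   OFF by default (it degrades accuracy by making colors inconsistent
#'   across photographs).
#' @param scale_range attribute scaling range.
#' @param cv a \code{\link{cv_config}}.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L,
                            extractor = extractor_config(seed = seed),
                            use_gm = TRUE, use_selection = FALSE,
                            select_threshold = 0.7,
                            normalize_colors = FALSE,
                            scale_range = c(0, 1),
                            cv = cv_config(seed = seed)) {
  structure(list(seed = as.integer(seed), extractor = extractor,
                 use_gm = use_gm, use_selection = use_selection,
                 select_threshold = select_threshold,
                 normalize_colors = normalize_colors,
                 scale_range = scale_range, cv = cv),
            class = "pipeline_config")
}

#' Run the full identification pipeline
#'
#' Extracts the 48-element feature vector of every image, optionally appends
#' the 34 Procrustes shape coordinates from the landmark configurations,
#' optionally screens features by F-score, and evaluates the classifier
#' under repeated random-subsampling cross-validation. Deterministic given
#' the config's seeds.
#'
#' @param images list of \code{\link{masked_image}} objects.
#' @param landmarks list of \code{\link{landmark_set}} objects aligned with
#'   \code{images} (may be \code{NULL} when \code{use_gm = FALSE}).
#' @param labels class labels aligned with \code{images}.
#' @param config a \code{\link{pipeline_config}}.
#' @param ids specimen ids; default taken from \code{landmarks} or numbered.
#' @return Object of class \code{fin_report}: \code{features} (labeled
#'   table used for CV), \code{fscores}, \code{selected} (kept columns),
#'   \code{palette_summary} (per-class mean of the 3 dominant colors),
#'   \code{cv} (\code{fin_cv}), \code{confusion} (\code{fin_confusion}),
#'   \code{importance} (RF only, else \code{NULL}), \code{manifest}.
#' @export
run_pipeline <- function(images, landmarks = NULL, labels, config = pipeline_config(),
                         ids = NULL) {
  n <- length(images)
  if (length(labels) != n) stop("stage input: labels misaligned with images")
  if (is.null(ids)) {
    ids <- if (!is.null(landmarks))
      vapply(landmarks, function(l) l$id, character(1))
    else sprintf("specimen_%03d", seq_len(n))
  }
  degenerate <- character(0)
  feats <- matrix(NA_real_, n, 48, dimnames = list(ids, feature_names()))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (img$degenerate) { degenerate <- c(degenerate, ids[i]); next }
    if (config$normalize_colors) img <- normalize_colors(img)
    feats[i, ] <- tryCatch(extract_features(img, config$extractor),
      error = function(e) stop("feature extraction failed for specimen ",
                               ids[i], ": ", conditionMessage(e)))
  }
  if (length(degenerate) > 0L)
    stop("degenerate (all-background) specimens: ",
         paste(degenerate, collapse = ", "))
  table <- labeled_feature_table(feats, labels)
  scores <- f_scores(table)
  selected <- colnames(feats)
  if (config$use_selection) {
    keep <- select_features(table, threshold = config$select_threshold,
                            scores = scores)
    selected <- colnames(feats)[keep]
    table <- labeled_feature_table(feats[, keep, drop = FALSE], labels)
  } else if (anyNA(feats)) {
    # degenerate color ratios are NA markers; drop the column rather than
    # the specimens
    ok <- !apply(is.na(table$X), 2, any)
    table <- labeled_feature_table(table$X[, ok, drop = FALSE], labels)
    selected <- colnames(table$X)
  }
  if (isTRUE(config$use_gm)) {
    if (is.null(landmarks)) stop("use_gm = TRUE but no landmarks supplied")
    fit <- gpa(landmarks)
    shapes <- procrustes_coordinates(fit)
    table <- combine_features(table, shapes)
  }
  cv <- repeated_holdout_cv(table, config$cv)
  cm <- confusion_matrix(cv$predictions, levels = cv$levels)
  importance <- NULL
  if (config$cv$classifier == "rf") {
    sc <- suppressWarnings(scale_features(table, range = config$scale_range))
    importance <- rf_importance(
      train_classifier(sc$train, config$cv, seed = config$seed))
  }
  pal3 <- palette_summary(images, labels, config$extractor)
  structure(list(features = table, fscores = scores, selected = selected,
                 palette_summary = pal3, cv = cv, confusion = cm,
                 importance = importance,
                 manifest = list(seed = config$seed,
                                 n = n, n_classes = nlevels(table$y),
                                 use_gm = config$use_gm,
                                 use_selection = config$use_selection,
                                 normalize_colors = config$normalize_colors,
                                 classifier = config$cv$classifier,
                                 n_reps = config$cv$n_reps,
                                 test_fraction = config$cv$test_fraction)),
            class = "fin_report")
}

#' @export
print.fin_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fin_report> %d specimens, %d classes, %s x %d reps\n",
              m$n, m$n_classes, toupper(m$classifier), m$n_reps))
  cat(sprintf("  features used: %d%s\n", ncol(x$features$X),
              if (m$use_gm) " (incl. 34 shape coordinates)" else ""))
  cat(sprintf("  CV accuracy: %.1f%% (s.d. %.1f)\n",
              x$cv$accuracy_mean, x$cv$accuracy_sd))
  invisible(x)
}

#' Per-class mean dominant-color palette
#'
#' Averages the RGB of the three most frequent quantized colors within each
#' class — the condensed palette view of how the classes differ in color.
#'
#' @param images list of \code{\link{masked_image}} objects.
#' @param labels aligned class labels.
#' @param config an \code{\link{extractor_config}}.
#' @return Data frame with class, color rank (0..2) and mean R, G, B.
#' @export
palette_summary <- function(images, labels, config = extractor_config()) {
  rows <- list()
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    acc <- matrix(0, 3, 3)
    for (i in idx) {
      pal <- quantize_palette(images[[i]], k = config$k, seed = config$seed)
      acc <- acc + as.matrix(pal[1:3, c("r", "g", "b")])
    }
    acc <- acc / length(idx)
    rows[[lv]] <- data.frame(class = lv, color = 0:2,
                             r = acc[, 1], g = acc[, 2], b = acc[, 3],
                             row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write a report bundle to disk
#'
#' Writes the combined feature table, F-score table, palette summary,
#' confusion matrix, accuracy summary, RF importance (when present) and a
#' manifest of all parameters, as plain CSV/text files.
#'
#' @param report a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fin_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(id = rownames(report$features$X),
                              label = report$features$y,
                              report$features$X, check.names = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = names(report$fscores),
                              f_score = report$fscores),
                   file.path(dir, "fscores.csv"), row.names = FALSE)
  utils::write.csv(report$palette_summary,
                   file.path(dir, "palette_summary.csv"), row.names = FALSE)
  cm <- report$confusion
  out <- rbind(cm$counts, Sum = cm$sums,
               `Accuracy(%)` = round(cm$class_accuracy, 2))
  utils::write.csv(out, file.path(dir, "confusion_matrix.csv"))
  writeLines(c(
    sprintf("classifier: %s", report$manifest$classifier),
    sprintf("accuracy_mean: %.4f", report$cv$accuracy_mean),
    sprintf("accuracy_sd: %.4f", report$cv$accuracy_sd),
    sprintf("overall_accuracy_pooled: %.4f", cm$overall_accuracy),
    sprintf("pooled_predictions: %d", nrow(report$cv$predictions))),
    file.path(dir, "accuracy_summary.txt"))
  if (!is.null(report$importance))
    utils::write.csv(report$importance, file.path(dir, "rf_importance.csv"),
                     row.names = FALSE)
  manifest <- vapply(report$manifest, function(v) paste(format(v), collapse = " "),
                     character(1))
  writeLines(paste0(names(manifest), ": ", manifest),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
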