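# F-score feature screening and min-max attribute scaling.

#' Build a labeled feature table
#'
#' @param X numeric matrix (n specimens x p features) or data frame.
#' @param y class labels, length n.
#' @return Object of class \code{labeled_feature_table} with elements
#'   \code{X} (matrix) and \code{y} (factor).
#' @export
labeled_feature_table <- function(X, y) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("feature table must have p > 0 features")
  if (nrow(X) != length(y)) stop("X rows and labels differ in length")
  if (!is.factor(y)) y <- factor(y)  # keep existing levels through splits
  structure(list(X = X, y = y), class = "labeled_feature_table")
}

#' @export
print.labeled_feature_table <- function(x, ...) {
  cat(sprintf("<labeled_feature_table> %d specimens x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), nlevels(x$y)))
  invisible(x)
}

#' F-score of one feature
#'
#' Between- to within-class variance ratio used to screen features before
#' classification: the sum over classes of the squared deviation of the
#' class mean from the global mean, divided by the sum over classes of the
#' (n_c - 1 denominator) sample variances. Higher scores mark features more
#' likely to discriminate the classes. Invariant under affine transforms of
#' the feature and under class relabeling.
#'
#' @param table a \code{\link{labeled_feature_table}}; every class must have
#'   at least 2 members.
#' @param i feature index or name.
#' @return The F-score; \code{Inf} (with a warning) when every class is
#'   constant in the feature.
#' @export
f_score <- function(table, i) {
  stopifnot(inherits(table, "labeled_feature_table"))
  x <- table$X[, i]
  if (anyNA(x)) stop("feature has missing values")
  cls <- split(x, table$y)
  if (any(lengths(cls) < 2L)) stop("every class needs n_c >= 2")
  gm <- mean(x)
  num <- sum(vapply(cls, function(v) (mean(v) - gm)^2, numeric(1)))
  den <- sum(vapply(cls, stats::var, numeric(1)))
  if (den == 0) {
    warning("all classes constant in feature; F-score is infinite")
    return(Inf)
  }
  num / den
}

#' F-scores of all features
#'
#' @param table a \code{\link{labeled_feature_table}}.
#' @param warn emit the infinite-score warning per degenerate feature.
#' @return Named numeric vector, one score per feature (NA-containing
#'   features are scored \code{NA}).
#' @export
f_scores <- function(table, warn = FALSE) {
  stopifnot(inherits(table, "labeled_feature_table"))
  out <- vapply(seq_len(ncol(table$X)), function(i) {
    if (anyNA(table$X[, i])) return(NA_real_)
    if (warn) f_score(table, i) else suppressWarnings(f_score(table, i))
  }, numeric(1))
  names(out) <- colnames(table$X)
  out
}

#' Select features by F-score threshold
#'
#' Keeps the features whose F-score is at least \code{threshold}, in their
#' original order. At the default threshold 0.7, a feature set with scores
#' (color ratio 0.42, entropy 0.98, edge 1.08, horizontal 0.93, diagonal
#' 0.46, vertical 1.15) drops the color ratio and the diagonal-line count.
#'
#' @param table a \code{\link{labeled_feature_table}}.
#' @param threshold minimum F-score (default 0.7).
#' @param scores optional precomputed scores (as from \code{\link{f_scores}}).
#' @return Integer vector of kept feature indices (empty, with a warning, if
#'   nothing passes).
#' @export
select_features <- function(table, threshold = 0.7, scores = NULL) {
  if (is.null(scores)) scores <- f_scores(table)
  keep <- which(!is.na(scores) & scores >= threshold)
  if (length(keep) == 0L) warning("no feature reaches the F-score threshold")
  keep
}

#' Min-max scale features, fitted on the training table only
#'
#' Fits a per-feature linear map sending the training minimum and maximum to
#' the bounds of \code{range}, and applies it to both tables. Test values
#' outside the training range map outside the bounds (no clipping), and
#' constant training features map to the lower bound.
#'
#' @param train a \code{\link{labeled_feature_table}} the map is fitted on.
#' @param apply_to optional second table the fitted map is applied to.
#' @param range \code{c(0, 1)} (default) or \code{c(-1, 1)}.
#' @return List with \code{train}, \code{apply_to} (scaled tables; the
#'   latter \code{NULL} if not supplied) and the fitted \code{min}/\code{max}
#'   vectors.
#' @export
scale_features <- function(train, apply_to = NULL, range = c(0, 1)) {
  stopifnot(inherits(train, "labeled_feature_table"))
  lo <- range[1]; hi <- range[2]
  mins <- apply(train$X, 2, min)
  maxs <- apply(train$X, 2, max)
  const <- maxs == mins
  if (any(const)) warning(sum(const), " constant feature(s) mapped to the lower bound")
  scale1 <- function(X) {
    out <- sweep(X, 2, mins)
    span <- maxs - mins
    span[const] <- 1
    out <- sweep(out, 2, span, "/") * (hi - lo) + lo
    out[, const] <- lo
    out
  }
  list(train = labeled_feature_table(scale1(train$X), train$y),
       apply_to = if (!is.null(apply_to))
         labeled_feature_table(scale1(apply_to$X), apply_to$y),
       min = mins, max = maxs, range = range)
}
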