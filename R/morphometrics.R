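# Landmark morphometrics: TPS file I/O and generalized Procrustes analysis
# (rotation-only, unit centroid size), yielding the 34 Procrustes
# coordinates appended to the image features.

#' Read landmark configurations from a TPS file
#'
#' Supported dialect: records starting \code{LM=17}, followed by 17
#' whitespace-separated \code{x y} lines, with optional \code{ID=} and
#' \code{IMAGE=} lines closing the record. Raster y-coordinates (y down) are
#' converted to Cartesian (y up) at read time by negation, matching the
#' digitizer convention in which a landmark's y-coordinate reads as vertical
#' height.
#'
#' @param path TPS file path.
#' @param invert_y negate y at read time (default \code{TRUE}).
#' @return List of \code{\link{landmark_set}} objects in file order.
#' @export
read_tps <- function(path, invert_y = TRUE) {
  if (!file.exists(path)) stop("cannot read TPS file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  out <- list(); i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("malformed TPS line ", i, ": expected LM= record header")
    rec <- rec + 1L
    nlm <- as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE))
    if (is.na(nlm) || nlm != 17L)
      stop("record ", rec, ": expected 17 landmarks, got ", nlm)
    coords <- matrix(NA_real_, 17, 2)
    for (j in 1:17) {
      i <- i + 1L
      parts <- strsplit(lines[i], "\\s+")[[1]]
      xy <- suppressWarnings(as.numeric(parts))
      if (length(xy) != 2L || anyNA(xy))
        stop("malformed coordinate at line ", i)
      coords[j, ] <- xy
    }
    id <- sprintf("specimen_%d", rec)
    while (i + 1L <= length(lines) &&
           grepl("^(ID|IMAGE|SCALE)\\s*=", lines[i + 1L], ignore.case = TRUE)) {
      i <- i + 1L
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
    }
    if (invert_y) coords[, 2] <- -coords[, 2]
    out[[rec]] <- landmark_set(coords, id = id)
    i <- i + 1L
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of \code{\link{read_tps}} (Cartesian y is negated back to raster
#' convention when \code{invert_y = TRUE}).
#'
#' @param configs list of \code{\link{landmark_set}} objects.
#' @param path output path.
#' @param invert_y negate y at write time (default \code{TRUE}).
#' @return \code{path}, invisibly.
#' @export
write_tps <- function(configs, path, invert_y = TRUE) {
  lines <- character(0)
  for (ls in configs) {
    co <- ls$coords
    if (invert_y) co[, 2] <- -co[, 2]
    lines <- c(lines, "LM=17",
               sprintf("%.6f %.6f", co[, 1], co[, 2]),
               paste0("ID=", ls$id))
  }
  writeLines(lines, path)
  invisible(path)
}

# center a k x 2 configuration and return it with its centroid size
center_scale <- function(co) {
  co <- sweep(co, 2, colMeans(co))
  cs <- sqrt(sum(co^2))
  if (cs < 1e-12) stop("degenerate configuration: all landmarks coincident")
  list(coords = co / cs, size = cs)
}

# least-squares rotation (no reflection) aligning A onto B; both centered
ls_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each configuration
#' is centered, scaled to unit centroid size and rotated (rotation only; no
#' reflection) onto the running consensus, which is re-estimated as the mean
#' configuration until its Frobenius change falls below \code{tol}. This
#' removes the non-shape variation (position, size, orientation), leaving
#' shape-only coordinates.
#'
#' @param configs list of \code{\link{landmark_set}} objects (>= 2).
#' @param tol consensus Frobenius-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return Object of class \code{gpa_fit}: \code{aligned} (n x 17 x 2
#'   array), \code{consensus} (17 x 2), \code{centroid_sizes},
#'   \code{iterations}, \code{converged}, \code{ids}.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (length(configs) < 2L) stop("GPA needs at least 2 configurations")
  n <- length(configs)
  ids <- vapply(configs, function(x) x$id, character(1))
  norm <- lapply(configs, function(x) center_scale(x$coords))
  sizes <- vapply(norm, function(x) x$size, numeric(1))
  A <- lapply(norm, function(x) x$coords)
  consensus <- A[[1]]
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- lapply(A, function(co) co %*% ls_rotation(co, consensus))
    newc <- Reduce(`+`, A) / n
    if (sqrt(sum((newc - consensus)^2)) < tol) {
      consensus <- newc; converged <- TRUE; break
    }
    consensus <- newc
  }
  aligned <- array(NA_real_, c(n, 17, 2),
                   dimnames = list(ids, NULL, c("x", "y")))
  for (i in seq_len(n)) aligned[i, , ] <- A[[i]]
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, iterations = it,
                 converged = converged, ids = ids),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit> %d configurations, %d iterations, %s\n",
              dim(x$aligned)[1], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Procrustes coordinate matrix
#'
#' Flattens an alignment into the n x 34 shape-variable matrix appended to
#' the image features: columns \code{ProcCoord_1x, ProcCoord_1y, ...,
#' ProcCoord_17y} (so \code{ProcCoord_5y} is the aligned y of landmark 5).
#'
#' @param result a converged \code{\link{gpa}} fit.
#' @return Numeric matrix, one row per specimen, 34 named columns; specimen
#'   ids as row names.
#' @export
procrustes_coordinates <- function(result) {
  stopifnot(inherits(result, "gpa_fit"))
  if (!result$converged) stop("GPA did not converge")
  n <- dim(result$aligned)[1]
  m <- matrix(NA_real_, n, 34)
  for (i in seq_len(n)) m[i, ] <- as.vector(t(result$aligned[i, , ]))
  colnames(m) <- as.vector(t(outer(paste0("ProcCoord_", 1:17),
                                   c("x", "y"), paste0)))
  rownames(m) <- result$ids
  m
}

#' Append shape variables to an image feature table
#'
#' Horizontal concatenation of the 48 extractor features and the 34
#' Procrustes coordinates into the combined 82-variable table. Specimen id
#' order must match exactly.
#'
#' @param features a \code{\link{labeled_feature_table}} whose \code{X} has
#'   specimen ids as row names.
#' @param shapes matrix from \code{\link{procrustes_coordinates}} (or an
#'   empty matrix, returning \code{features} unchanged with a warning).
#' @return A combined \code{\link{labeled_feature_table}}.
#' @export
combine_features <- function(features, shapes) {
  stopifnot(inherits(features, "labeled_feature_table"))
  if (is.null(shapes) || length(shapes) == 0L || nrow(shapes) == 0L) {
    warning("empty shape matrix; returning feature table unchanged")
    return(features)
  }
  fid <- rownames(features$X); sid <- rownames(shapes)
  if (!is.null(fid) && !is.null(sid) && !identical(fid, sid)) {
    bad <- which(fid != sid)
    stop("specimen id mismatch at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (nrow(features$X) != nrow(shapes))
    stop("feature and shape tables differ in row count")
  labeled_feature_table(cbind(features$X, shapes), features$y)
}
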