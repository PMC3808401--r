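#' Sentinel background color
#'
#' Masked-out background pixels carry this exact color (pure magenta); the
#' feature extractor ignores them. Synthetic fish bodies never use it.
#'
#' @return Integer RGB triple \code{c(255, 0, 255)}.
#' @export
sentinel_color <- function() c(255L, 0L, 255L)

#' Construct a masked image
#'
#' A masked image couples an 8-bit RGB raster with a logical foreground mask.
#' Background pixels are held at the sentinel color and contribute to no
#' downstream statistic.
#'
#' @param pixels integer array \code{H x W x 3} with values in \code{[0, 255]}.
#' @param mask logical \code{H x W} matrix, \code{TRUE} = foreground. If
#'   missing, derived as "pixel differs from the sentinel".
#' @param sentinel RGB triple marking background pixels.
#' @return An object of class \code{masked_image} with elements
#'   \code{pixels}, \code{mask}, \code{sentinel} and a \code{degenerate}
#'   flag (no foreground pixels).
#' @export
masked_image <- function(pixels, mask = NULL, sentinel = sentinel_color()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L))
    stop("pixel values must lie in [0, 255]")
  if (is.null(mask)) {
    mask <- !(pixels[, , 1] == sentinel[1] &
              pixels[, , 2] == sentinel[2] &
              pixels[, , 3] == sentinel[3])
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(pixels)[1:2]))
    stop("mask must be a logical H x W matrix matching pixels")
  degenerate <- !any(mask)
  if (degenerate) warning("image has zero foreground pixels (degenerate)")
  structure(
    list(pixels = pixels, mask = mask, sentinel = as.integer(sentinel),
         degenerate = degenerate),
    class = "masked_image"
  )
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<masked_image> %d x %d px, %d foreground (%.1f%%)%s\n",
              d[1], d[2], sum(x$mask), 100 * mean(x$mask),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
dim.masked_image <- function(x) dim(x$pixels)

# n x 3 matrix of foreground pixel values (row-major over the mask)
foreground_pixels <- function(image) {
  stopifnot(inherits(image, "masked_image"))
  cbind(image$pixels[, , 1][image$mask],
        image$pixels[, , 2][image$mask],
        image$pixels[, , 3][image$mask])
}

assert_foreground <- function(image) {
  if (!any(image$mask)) stop("empty foreground")
  invisible(TRUE)
}

#' Load an image and derive its foreground mask
#'
#' Reads a PNG (or, if the EBImage package is available, a JPEG) and marks as
#' background every pixel within \code{tol} intensity units (L-infinity) of
#' the sentinel. Lossless fixtures need \code{tol = 0}; JPEG compression
#' perturbs the sentinel, so a small tolerance (8 units) is applied to JPEGs
#' by default.
#'
#' @param path path to a PNG or JPEG file.
#' @param sentinel background sentinel RGB triple.
#' @param tol L-infinity tolerance around the sentinel; \code{NULL} picks 0
#'   for PNG and 8 for JPEG.
#' @return A \code{\link{masked_image}}; degenerate (all-background) images
#'   are flagged with a warning.
#' @export
load_image <- function(path, sentinel = sentinel_color(), tol = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package")
    img <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(img), c(2, 1, 3))  # EBImage is W x H x C
    if (is.null(tol)) tol <- 8
  } else {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
    if (is.null(tol)) tol <- 0
  }
  px <- array(as.integer(round(a * 255)), dim = dim(a))[, , 1:3, drop = FALSE]
  d <- abs(sweep(px, 3, as.integer(sentinel)))
  near <- apply(d, c(1, 2), max) <= tol
  # snap near-sentinel pixels to the exact sentinel so mask <-> sentinel holds
  for (ch in 1:3) {
    pl <- px[, , ch]
    pl[near] <- sentinel[ch]
    px[, , ch] <- pl
  }
  masked_image(px, mask = !near, sentinel = sentinel)
}

#' Write a masked image as PNG
#'
#' Background pixels are written with the exact sentinel color, so the file
#' round-trips through \code{\link{load_image}} bit-identically.
#'
#' @param image a \code{\link{masked_image}}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
save_masked_image <- function(image, path) {
  stopifnot(inherits(image, "masked_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Mask the background of a raw image
#'
#' Contract stage for background removal: pixels outside the estimated
#' subject are set to the sentinel. The bundled reference segmenter
#' (\code{method = "threshold"}) is a border-seeded color-distance threshold:
#' the background color is estimated from the border pixels of \code{rect}'s
#' complement, and pixels within \code{tol} (Euclidean RGB) of it are marked
#' background. Graph-cut-class algorithms can be plugged in by passing a
#' function as \code{method}.
#'
#' @param pixels raw \code{H x W x 3} integer raster in \code{[0, 255]}, or a
#'   \code{\link{masked_image}} (returned unchanged: idempotence).
#' @param rect bounding box \code{c(row1, col1, row2, col2)} known to contain
#'   the subject; pixels outside it are always background.
#' @param method \code{"threshold"} or a function
#'   \code{(pixels, rect) -> logical mask}.
#' @param tol Euclidean RGB distance below which a pixel counts as
#'   background (threshold method).
#' @param sentinel background sentinel RGB triple.
#' @return A \code{\link{masked_image}}.
#' @export
remove_background <- function(pixels, rect = NULL, method = "threshold",
                              tol = 40, sentinel = sentinel_color()) {
  if (inherits(pixels, "masked_image")) return(pixels)
  storage.mode(pixels) <- "integer"
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (is.null(rect)) rect <- c(1L, 1L, h, w)
  if (rect[1] < 1 || rect[2] < 1 || rect[3] > h || rect[4] > w ||
      rect[1] > rect[3] || rect[2] > rect[4])
    stop("rect must lie inside the image")
  if (is.function(method)) {
    fg <- method(pixels, rect)
  } else if (identical(method, "threshold")) {
    border <- rbind(
      cbind(1L, seq_len(w)), cbind(h, seq_len(w)),
      cbind(seq_len(h), 1L), cbind(seq_len(h), w))
    bg_col <- colMeans(cbind(pixels[, , 1][border],
                             pixels[, , 2][border],
                             pixels[, , 3][border]))
    d2 <- (pixels[, , 1] - bg_col[1])^2 +
          (pixels[, , 2] - bg_col[2])^2 +
          (pixels[, , 3] - bg_col[3])^2
    fg <- d2 > tol^2
  } else stop("unknown segmentation method: ", method)
  inside <- matrix(FALSE, h, w)
  inside[rect[1]:rect[3], rect[2]:rect[4]] <- TRUE
  fg <- fg & inside
  if (!any(fg)) stop("segmentation failed")
  out <- pixels
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[!fg] <- sentinel[ch]
    out[, , ch] <- pl
  }
  masked_image(out, mask = fg, sentinel = sentinel)
}

#' Per-channel linear stretch of foreground intensities
#'
#' Stretches each RGB channel of the foreground linearly to the full
#' \code{[0, 255]} range. This image-wise normalization is applied
#' independently per photograph, which makes colors inconsistent across a
#' collection; it degraded downstream classification in practice and is OFF
#' by default throughout the pipeline.
#'
#' @param image a \code{\link{masked_image}}.
#' @return A \code{\link{masked_image}} with stretched foreground; channels
#'   with a single intensity are left unchanged (with a warning when all
#'   three are constant).
#' @export
normalize_colors <- function(image) {
  stopifnot(inherits(image, "masked_image"))
  assert_foreground(image)
  px <- image$pixels
  touched <- FALSE
  for (ch in 1:3) {
    v <- px[, , ch][image$mask]
    lo <- min(v); hi <- max(v)
    if (hi == lo) next
    touched <- TRUE
    pl <- px[, , ch]
    pl[image$mask] <- as.integer(round((v - lo) / (hi - lo) * 255))
    px[, , ch] <- pl
  }
  if (!touched) warning("constant-color foreground; normalization is a no-op")
  masked_image(px, mask = image$mask, sentinel = image$sentinel)
}
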