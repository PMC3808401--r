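# The 48-element feature vector: 7-color quantized palette in RGB and HSV
# (42), dominant/second color pixel-count ratio (1), grayscale Shannon
# entropy (1), size-normalized Canny edge-pixel count (1), and straight
# horizontal/diagonal/vertical segment counts (3).

#' Names of the 48 extractor features, in canonical order
#'
#' \code{Color_<j>_<c>} gives channel \code{c} (r, g, b, h, s, v; all scaled
#' to \code{[0, 1]}) of the j-th most frequent quantized color (j = 0..6),
#' followed by \code{color_ratio}, \code{entropy}, \code{edge_count} and the
#' straight-segment counts \code{X0_deg_lines} (horizontal),
#' \code{X45_deg_lines} (diagonal), \code{X90_deg_lines} (vertical).
#'
#' @return Character vector of length 48.
#' @export
feature_names <- function() {
  c(as.vector(t(outer(paste0("Color_", 0:6, "_"),
                      c("r", "g", "b", "h", "s", "v"), paste0))),
    "color_ratio", "entropy", "edge_count",
    "X0_deg_lines", "X45_deg_lines", "X90_deg_lines")
}

#' Quantize the foreground into a dominant-color palette
#'
#' Optimum-palette color quantization of the foreground pixels into \code{k}
#' representative colors by k-means in RGB space, ordered by decreasing
#' pixel count. Background (sentinel) pixels are excluded entirely. When the
#' foreground holds at most \code{k} distinct colors they are returned
#' exactly (no clustering) and unused slots are padded with the last color
#' at count 0, keeping the palette length fixed.
#'
#' @param image a \code{\link{masked_image}}.
#' @param k palette size (default 7).
#' @param seed seed for the k-means initialization; fixed seed gives a
#'   deterministic palette.
#' @return Object of class \code{fin_palette}: data frame with columns
#'   \code{r, g, b} (0–255), \code{h, s, v} (0–1) and \code{count},
#'   descending by count.
#' @export
quantize_palette <- function(image, k = 7L, seed = 1L) {
  assert_foreground(image)
  px <- foreground_pixels(image)
  key <- px[, 1] * 65536 + px[, 2] * 256 + px[, 3]
  tab <- sort(table(key), decreasing = TRUE)
  if (length(tab) <= k) {
    keys <- as.numeric(names(tab))
    centers <- cbind(keys %/% 65536, (keys %/% 256) %% 256, keys %% 256)
    counts <- as.vector(tab)
    if (length(counts) < k) {
      pad <- k - length(counts)
      centers <- rbind(centers, matrix(rep(centers[nrow(centers), ], pad),
                                       pad, 3, byrow = TRUE))
      counts <- c(counts, rep(0L, pad))
    }
  } else {
    # canonical ordering makes the result invariant to pixel positions
    px <- px[order(key), , drop = FALSE]
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(px, centers = k, iter.max = 100, nstart = 3,
                    algorithm = "Lloyd"))
    o <- order(km$size, decreasing = TRUE)
    centers <- km$centers[o, , drop = FALSE]
    counts <- km$size[o]
  }
  hsv <- t(grDevices::rgb2hsv(t(centers), maxColorValue = 255))
  pal <- data.frame(r = centers[, 1], g = centers[, 2], b = centers[, 3],
                    h = hsv[, 1], s = hsv[, 2], v = hsv[, 3],
                    count = as.integer(counts))
  rownames(pal) <- paste0("Color_", seq_len(k) - 1)
  class(pal) <- c("fin_palette", "data.frame")
  pal
}

#' @export
print.fin_palette <- function(x, ...) {
  cat(sprintf("<fin_palette> %d colors over %d foreground pixels\n",
              nrow(x), sum(x$count)))
  print.data.frame(cbind(round(as.data.frame(x)[, 1:3]),
                         round(as.data.frame(x)[, 4:6], 3),
                         count = x$count))
  invisible(x)
}

#' Ratio of the two most frequent color counts
#'
#' Pixel count of the most frequent quantized color divided by that of the
#' second most frequent; e.g. 600 brown and 500 blue pixels give 1.2. A
#' proxy for how strongly one color dominates, hence for stripe structure.
#'
#' @param palette a \code{\link{quantize_palette}} result.
#' @return Ratio (>= 1 when defined).
#' @export
color_ratio <- function(palette) {
  stopifnot(inherits(palette, "fin_palette"))
  if (nrow(palette) < 2L || palette$count[2] <= 0L)
    stop("degenerate palette")
  palette$count[1] / palette$count[2]
}

#' Foreground grayscale histogram
#'
#' Fraction of foreground pixels at each 8-bit intensity after BT.601
#' grayscale conversion.
#'
#' @param image a \code{\link{masked_image}}.
#' @return Numeric vector of length 256 summing to 1.
#' @export
gray_histogram <- function(image) {
  assert_foreground(image)
  g <- round(gray_bt601(image$pixels))[image$mask]
  p <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p / sum(p)
}

#' Shannon entropy of the foreground grayscale histogram
#'
#' \eqn{-\sum_i p_i \log_2 p_i} over the 256-bin foreground intensity
#' histogram, with \eqn{0 \log 0 = 0}; a proxy for stripe-pattern
#' complexity. Ranges over \code{[0, 8]} bits for 8-bit intensities.
#'
#' @param image a \code{\link{masked_image}}.
#' @return Entropy in bits.
#' @export
entropy <- function(image) {
  p <- gray_histogram(image)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Size-normalized Canny edge-pixel count
#'
#' Canny edge map of the grayscale image; edge pixels on the foreground are
#' counted and divided by the foreground pixel count, so larger fish (whose
#' raw edge totals grow with body size) are comparable with smaller ones.
#'
#' @param image a \code{\link{masked_image}}.
#' @param low,high Canny hysteresis thresholds (8-bit intensity units).
#' @return Edge pixels per foreground pixel (dimensionless).
#' @export
edge_pixel_count <- function(image, low = 50, high = 150) {
  assert_foreground(image)
  e <- canny_edges(gray_bt601(image$pixels), low = low, high = high)
  sum(e & image$mask) / sum(image$mask)
}

#' Straight-line counts at 45-degree granularity
#'
#' Detects straight segments on the foreground-restricted Canny edge map and
#' bins them by orientation: horizontal (~0 deg), diagonal (~45/135 deg) and
#' vertical (~90 deg).
#'
#' @param image a \code{\link{masked_image}}.
#' @param low,high Canny hysteresis thresholds.
#' @param min_length minimum segment span in pixels.
#' @param max_gap largest tolerated within-segment gap in pixels.
#' @return Named integer vector \code{c(horizontal, diagonal, vertical)}.
#' @export
line_features <- function(image, low = 50, high = 150,
                          min_length = 15, max_gap = 3) {
  stopifnot(inherits(image, "masked_image"))
  e <- canny_edges(gray_bt601(image$pixels), low = low, high = high)
  e <- e & image$mask
  hough_segment_counts(e, min_length = min_length, max_gap = max_gap)
}

#' Extractor configuration
#'
#' @param k palette size.
#' @param canny_low,canny_high Canny hysteresis thresholds.
#' @param hough_min_length,hough_max_gap segment-detector parameters.
#' @param seed quantizer seed.
#' @return A list of extractor parameters.
#' @export
extractor_config <- function(k = 7L, canny_low = 50, canny_high = 150,
                             hough_min_length = 15, hough_max_gap = 3,
                             seed = 1L) {
  list(k = as.integer(k), canny_low = canny_low, canny_high = canny_high,
       hough_min_length = hough_min_length, hough_max_gap = hough_max_gap,
       seed = as.integer(seed))
}

#' Extract the 48-element feature vector of one image
#'
#' Computes, in fixed order: the 42 palette features (RGB and HSV of the 7
#' most frequent quantized colors, all scaled to \code{[0, 1]}), the color
#' ratio, the grayscale entropy, the normalized edge-pixel count and the
#' three straight-segment counts. A degenerate color ratio (second color
#' count 0) is recorded as \code{NA} rather than aborting the vector.
#'
#' @param image a \code{\link{masked_image}}.
#' @param config an \code{\link{extractor_config}}.
#' @return Named numeric vector of length 48 (see \code{\link{feature_names}}).
#' @export
extract_features <- function(image, config = extractor_config()) {
  assert_foreground(image)
  pal <- quantize_palette(image, k = config$k, seed = config$seed)
  colors <- as.vector(t(cbind(pal$r / 255, pal$g / 255, pal$b / 255,
                              pal$h, pal$s, pal$v)))
  ratio <- if (pal$count[2] > 0L) color_ratio(pal) else NA_real_
  ent <- entropy(image)
  edges <- canny_edges(gray_bt601(image$pixels),
                       low = config$canny_low, high = config$canny_high)
  fg_edges <- edges & image$mask
  edge_norm <- sum(fg_edges) / sum(image$mask)
  lines <- hough_segment_counts(fg_edges,
                                min_length = config$hough_min_length,
                                max_gap = config$hough_max_gap)
  out <- c(colors, ratio, ent, edge_norm, as.numeric(lines))
  names(out) <- feature_names()
  out
}

#' Extract features for a list of images
#'
#' @param images list of \code{\link{masked_image}} objects.
#' @param config an \code{\link{extractor_config}}.
#' @param ids optional specimen ids used as row names.
#' @return Numeric matrix, one row per image, 48 named columns.
#' @export
extract_feature_table <- function(images, config = extractor_config(),
                                  ids = NULL) {
  m <- t(vapply(images, extract_features, numeric(48), config = config))
  colnames(m) <- feature_names()
  if (!is.null(ids)) rownames(m) <- ids
  m
}
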