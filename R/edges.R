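# Edge detection and straight-segment counting on small 8-bit rasters.
# Implemented in-package: Canny (Gaussian smoothing, Sobel gradients,
# non-maximum suppression, hysteresis thresholding) and a deterministic
# scan-line straight-segment counter at 45-degree angular granularity.

# ITU-R BT.601 luma from an H x W x 3 integer raster -> H x W double matrix
gray_bt601 <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# shift a matrix by (dr, dc), replicating the border
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian smoothing with border replication
gaussian_smooth <- function(m, sigma = 1.4) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- m * 0
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, i - r - 1L, 0L)
  m2 <- out; out <- m * 0
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, 0L, i - r - 1L)
  out
}

#' Canny edge map
#'
#' Classic Canny detector on an 8-bit grayscale matrix: Gaussian smoothing,
#' Sobel gradients, non-maximum suppression with gradient direction
#' quantized to 45 degrees, and double-threshold hysteresis (weak edge
#' pixels survive only when 8-connected to a strong one).
#'
#' @param gray numeric matrix of intensities in \code{[0, 255]}.
#' @param low,high hysteresis thresholds on raw Sobel gradient magnitude
#'   (the OpenCV Canny threshold convention; an intensity step of height d
#'   produces a magnitude near 4d).
#' @param sigma Gaussian smoothing scale in pixels.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(gray, low = 50, high = 150, sigma = 1.4) {
  g <- gaussian_smooth(gray, sigma)
  # Sobel
  gx <- (shift_mat(g, 0, -1) - shift_mat(g, 0, 1)) * 2 +
        (shift_mat(g, -1, -1) - shift_mat(g, -1, 1)) +
        (shift_mat(g, 1, -1) - shift_mat(g, 1, 1))
  gy <- (shift_mat(g, -1, 0) - shift_mat(g, 1, 0)) * 2 +
        (shift_mat(g, -1, -1) - shift_mat(g, 1, -1)) +
        (shift_mat(g, -1, 1) - shift_mat(g, 1, 1))
  # raw Sobel magnitude (OpenCV threshold convention); rounded so that
  # non-maximum-suppression ties on flat regions do not depend on
  # floating-point summation order (keeps the map rotation-equivariant)
  mag <- round(sqrt(gx^2 + gy^2), 6)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  # non-maximum suppression along the quantized gradient direction
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4
  n1 <- mag * 0; n2 <- mag * 0
  sel <- sector == 0  # gradient ~horizontal -> compare left/right
  n1[sel] <- shift_mat(mag, 0, -1)[sel]; n2[sel] <- shift_mat(mag, 0, 1)[sel]
  sel <- sector == 1  # 45 deg
  n1[sel] <- shift_mat(mag, -1, 1)[sel]; n2[sel] <- shift_mat(mag, 1, -1)[sel]
  sel <- sector == 2  # vertical gradient -> compare up/down
  n1[sel] <- shift_mat(mag, -1, 0)[sel]; n2[sel] <- shift_mat(mag, 1, 0)[sel]
  sel <- sector == 3  # 135 deg
  n1[sel] <- shift_mat(mag, -1, -1)[sel]; n2[sel] <- shift_mat(mag, 1, 1)[sel]
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low & mag < high
  # hysteresis: grow strong set through 8-connected weak pixels
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(strong, dr, dc)
    }
    grown <- strong | (grown & weak)
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

# count maximal runs of TRUE pixels along one scan family.
# groups: integer grouping (one value per edge pixel), pos: position along
# the scan within the group. A run is a maximal set of pixels in one group
# whose consecutive positions differ by <= max_gap + 1; runs spanning
# >= min_length pixels count as one segment.
count_runs <- function(groups, pos, min_length, max_gap) {
  if (length(groups) == 0L) return(0L)
  o <- order(groups, pos)
  g <- groups[o]; p <- pos[o]
  new_run <- c(TRUE, diff(p) > (max_gap + 1) | diff(g) != 0)
  run_id <- cumsum(new_run)
  span <- tapply(p, run_id, function(v) max(v) - min(v) + 1)
  sum(span >= min_length)
}

#' Count straight segments by orientation
#'
#' Deterministic scan-line analogue of a probabilistic Hough segment
#' detector at 45-degree angular granularity: edge pixels are scanned along
#' rows (horizontal segments), columns (vertical) and both diagonal
#' families, and maximal runs spanning at least \code{min_length} pixels
#' with gaps up to \code{max_gap} count as one segment each.
#'
#' @param edges logical edge matrix.
#' @param min_length minimum segment span in pixels.
#' @param max_gap largest tolerated gap inside a segment, pixels.
#' @return Integer vector \code{c(horizontal, diagonal, vertical)}.
#' @export
hough_segment_counts <- function(edges, min_length = 15, max_gap = 3) {
  idx <- which(edges, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(horizontal = 0L, diagonal = 0L, vertical = 0L))
  r <- idx[, 1]; c <- idx[, 2]
  n_h <- count_runs(r, c, min_length, max_gap)          # along rows
  n_v <- count_runs(c, r, min_length, max_gap)          # along columns
  n_d <- count_runs(r + c, c, min_length, max_gap) +    # anti-diagonals
         count_runs(r - c, c, min_length, max_gap)      # main diagonals
  c(horizontal = as.integer(n_h), diagonal = as.integer(n_d),
    vertical = as.integer(n_v))
}
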