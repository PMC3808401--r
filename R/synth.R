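# Synthetic fish fixtures: elliptical body on a sentinel background, a small
# class-specific palette laid out in vertical bands, optional stripe bars in
# the least frequent palette color, Gaussian pixel noise, and a 17-landmark
# template scaled to the body box plus Gaussian landmark jitter.

#' 17-landmark lateral fish template
#'
#' Generic lateral-outline template on the unit square (x right, y up).
#' Landmark 1 is the mouth tip, landmark 5 the dorsal apex and landmark 10
#' the ventral apex, so the y-coordinates of 1, 5 and 10 track mouth-tip
#' height and body height once the template is scaled to a class's body box.
#'
#' @return A 17 x 2 matrix of (x, y) coordinates in \code{[0, 1]}.
#' @export
fish_landmark_template <- function() {
  m <- matrix(c(
    0.00, 0.50,   # 1  mouth tip
    0.06, 0.64,   # 2  snout / forehead
    0.16, 0.74,   # 3  nape
    0.30, 0.81,   # 4  dorsal-fin origin
    0.46, 0.87,   # 5  dorsal apex (y tracks body height)
    0.62, 0.78,   # 6  dorsal-fin end
    0.76, 0.64,   # 7  caudal peduncle, top
    0.88, 0.57,   # 8  caudal-fin base, top
    0.88, 0.43,   # 9  caudal-fin base, bottom
    0.46, 0.13,   # 10 ventral apex (y tracks body height)
    0.76, 0.36,   # 11 caudal peduncle, bottom
    0.62, 0.22,   # 12 anal-fin origin
    0.30, 0.19,   # 13 pelvic-fin insertion
    0.16, 0.27,   # 14 isthmus
    0.06, 0.37,   # 15 lower jaw
    0.13, 0.55,   # 16 eye center
    0.26, 0.50),  # 17 operculum / pectoral insertion
    ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' Define a synthetic fish class
#'
#' A class specification fixes everything the generator needs: a dominant
#' palette with body-coverage proportions, a stripe pattern, the body box in
#' pixels, a landmark template and the two noise scales.
#'
#' @param label class label (species/sex tag, e.g. \code{"toc_m"}).
#' @param palette list of \code{list(rgb = integer triple, prop = fraction)};
#'   proportions must sum to 1 (tolerance 1e-9) and no entry may be the
#'   sentinel magenta.
#' @param stripe_count number of stripe bars (>= 0).
#' @param stripe_orientation \code{"vertical"}, \code{"horizontal"} or
#'   \code{"diagonal"}.
#' @param body_width_px,body_height_px body ellipse axes in pixels.
#' @param landmark_mean 17 x 2 template on the unit square; defaults to
#'   \code{\link{fish_landmark_template}}.
#' @param landmark_noise_sd landmark jitter s.d. in pixels.
#' @param color_noise_sd additive Gaussian pixel noise s.d. in intensity
#'   units (0–255 scale).
#' @return An object of class \code{class_spec}.
#' @export
class_spec <- function(label, palette,
                       stripe_count = 0L,
                       stripe_orientation = c("vertical", "horizontal",
                                              "diagonal"),
                       body_width_px = 180, body_height_px = 64,
                       landmark_mean = fish_landmark_template(),
                       landmark_noise_sd = 1, color_noise_sd = 0) {
  stripe_orientation <- match.arg(stripe_orientation)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  props <- vapply(palette, function(p) p$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-9)
    stop("palette proportions must sum to 1")
  for (p in palette) {
    if (length(p$rgb) != 3L || any(p$rgb < 0) || any(p$rgb > 255))
      stop("palette entries must be RGB triples in [0, 255]")
    if (all(as.integer(p$rgb) == sentinel_color()))
      stop("palette may not contain the sentinel magenta")
  }
  if (body_width_px <= 0 || body_height_px <= 0)
    stop("body dimensions must be positive")
  if (!is.matrix(landmark_mean) || !identical(dim(landmark_mean), c(17L, 2L)))
    stop("landmark_mean must be a 17 x 2 matrix")
  if (stripe_count < 0) stop("stripe_count must be >= 0")
  structure(
    list(label = label, palette = palette,
         stripe_count = as.integer(stripe_count),
         stripe_orientation = stripe_orientation,
         body_width_px = body_width_px, body_height_px = body_height_px,
         landmark_mean = landmark_mean,
         landmark_noise_sd = landmark_noise_sd,
         color_noise_sd = color_noise_sd),
    class = "class_spec")
}

#' @export
print.class_spec <- function(x, ...) {
  cat(sprintf("<class_spec> %s: %d colors, %d %s stripes, body %gx%g px\n",
              x$label, length(x$palette), x$stripe_count,
              x$stripe_orientation, x$body_width_px, x$body_height_px))
  invisible(x)
}

#' Default 12-class synthetic study design
#'
#' Twelve classes emulating a 12-class (9 species, sexes split) study design:
#' each class has ~3 dominant body colors, a class-specific stripe pattern
#' and a class-specific body height, with mild landmark jitter and pixel
#' noise.
#'
#' @param disjoint_palettes if \code{TRUE} every class gets its own color
#'   family (classes separable from color alone); if \code{FALSE} classes
#'   share palettes pairwise and differ within a pair only in body height,
#'   so shape information is required to separate them.
#' @param color_noise_sd,landmark_noise_sd noise scales passed to every
#'   class.
#' @return A list of 12 \code{\link{class_spec}} objects.
#' @export
default_class_specs <- function(disjoint_palettes = TRUE,
                                color_noise_sd = 8, landmark_noise_sd = 1.5) {
  labels <- c("gm_f", "lf_m", "mv_f", "pe_m", "pf_f", "pg_f",
              "tg_f", "tg_m", "tm_f", "tm_m", "toc_f", "toc_m")
  # 12 well-separated color families (base hue per class)
  base <- list(
    c(150,  90,  40), c( 40,  90, 200), c( 60,  60,  60), c(230, 200,  60),
    c(180, 120, 160), c( 60, 160,  70), c(200,  80,  60), c( 80, 200, 200),
    c(120,  60, 160), c(210, 140,  20), c( 90, 130,  90), c( 30, 40, 120))
  heights <- c(52, 56, 60, 64, 68, 72, 52, 72, 56, 68, 60, 76)
  stripes <- rep(c(0L, 2L, 3L, 4L), 3)
  orient  <- rep(c("vertical", "vertical", "horizontal", "vertical"), 3)
  specs <- vector("list", 12)
  for (i in 1:12) {
    b <- if (disjoint_palettes) base[[i]] else base[[((i - 1) %/% 2) + 1]]
    pal <- list(
      list(rgb = pmin(255, pmax(0, b)),            prop = 0.55),
      list(rgb = pmin(255, pmax(0, b + 60)),       prop = 0.30),
      list(rgb = pmin(255, pmax(0, round(b/2))),   prop = 0.15))
    specs[[i]] <- class_spec(
      label = labels[i], palette = pal,
      stripe_count = stripes[i], stripe_orientation = orient[i],
      body_width_px = 180, body_height_px = heights[i],
      landmark_noise_sd = landmark_noise_sd,
      color_noise_sd = color_noise_sd)
  }
  specs
}

#' Generate one synthetic masked fish image
#'
#' Draws an axis-aligned elliptical body filled with the class palette in its
#' stated proportions (laid out as bands along the body axis), overlays
#' stripe bars in the least frequent palette color, adds i.i.d. Gaussian
#' intensity noise clipped to \code{[0, 255]}, and sets every non-body pixel
#' to the sentinel magenta. Pure function of \code{(spec, seed)}.
#'
#' @param spec a \code{\link{class_spec}}.
#' @param seed integer seed; the same seed reproduces the image bit-for-bit.
#' @param canvas \code{c(height, width)} in pixels; must exceed the body box.
#' @return A \code{\link{masked_image}}.
#' @export
generate_fish_image <- function(spec, seed = 1L, canvas = c(96L, 256L)) {
  stopifnot(inherits(spec, "class_spec"))
  h <- canvas[1]; w <- canvas[2]
  if (spec$body_width_px > w || spec$body_height_px > h)
    stop("spec exceeds canvas")
  set.seed(seed)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- spec$body_width_px / 2; b <- spec$body_height_px / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
  n_fg <- sum(inside)
  if (n_fg == 0L) stop("spec exceeds canvas")

  # proportions realized as vertical bands: order foreground pixels by
  # column (then row) and cut at cumulative rounded counts
  ord <- order(cc[inside], rr[inside])
  props <- vapply(spec$palette, function(p) p$prop, numeric(1))
  counts <- floor(cumsum(props) * n_fg + 0.5)
  counts <- diff(c(0, counts))
  counts[length(counts)] <- n_fg - sum(counts[-length(counts)])
  color_idx_fg <- rep(seq_along(props), counts)[order(ord)]

  # stripe bars in the least frequent palette color
  if (spec$stripe_count > 0L) {
    k <- spec$stripe_count
    wbar <- spec$body_width_px / (2 * k + 1)
    stripe_col_idx <- which.min(props)
    pos <- switch(spec$stripe_orientation,
                  vertical   = cc[inside] - (cx - a),
                  horizontal = (rr[inside] - (cy - b)) *
                               (2 * k + 1) / (2 * k + 1) *
                               spec$body_width_px / spec$body_height_px,
                  diagonal   = (cc[inside] - (cx - a)) +
                               (rr[inside] - (cy - b)))
    band <- floor(pos / wbar)
    in_bar <- band %% 2 == 1
    color_idx_fg[in_bar] <- stripe_col_idx
  }

  px <- array(0L, c(h, w, 3))
  rgbm <- t(vapply(spec$palette, function(p) as.numeric(p$rgb), numeric(3)))
  fg_lin <- which(inside)
  for (ch in 1:3) {
    plane <- matrix(as.numeric(sentinel_color()[ch]), h, w)
    vals <- rgbm[color_idx_fg, ch]
    if (spec$color_noise_sd > 0)
      vals <- vals + stats::rnorm(n_fg, 0, spec$color_noise_sd)
    vals <- pmin(255, pmax(0, round(vals)))
    # avoid noise accidentally producing the exact sentinel inside the body
    plane[fg_lin] <- vals
    px[, , ch] <- plane
  }
  # guard: any foreground pixel that landed exactly on the sentinel triple
  hit <- inside & px[, , 1] == 255L & px[, , 2] == 0L & px[, , 3] == 255L
  if (any(hit)) { pl <- px[, , 3]; pl[hit] <- 254L; px[, , 3] <- pl }
  storage.mode(px) <- "integer"
  masked_image(px, mask = inside, sentinel = sentinel_color())
}

#' Generate one synthetic landmark configuration
#'
#' Scales the class landmark template to the body box and adds i.i.d.
#' Gaussian jitter of \code{landmark_noise_sd} pixels to both coordinates.
#' Pure function of \code{(spec, seed)}.
#'
#' @param spec a \code{\link{class_spec}}.
#' @param seed integer seed.
#' @param id specimen id attached to the configuration.
#' @return A \code{landmark_set}: list with \code{coords} (17 x 2 matrix,
#'   Cartesian y-up) and \code{id}.
#' @export
generate_landmarks <- function(spec, seed = 1L, id = spec$label) {
  stopifnot(inherits(spec, "class_spec"))
  set.seed(seed)
  coords <- spec$landmark_mean
  coords[, 1] <- coords[, 1] * spec$body_width_px
  coords[, 2] <- coords[, 2] * spec$body_height_px
  if (spec$landmark_noise_sd > 0)
    coords <- coords + matrix(stats::rnorm(34, 0, spec$landmark_noise_sd),
                              17, 2)
  landmark_set(coords, id = id)
}

#' Construct a landmark set
#'
#' @param coords 17 x 2 numeric matrix of (x, y) coordinates (Cartesian,
#'   y up), pixel units.
#' @param id specimen id.
#' @return An object of class \code{landmark_set}.
#' @export
landmark_set <- function(coords, id = "specimen") {
  coords <- as.matrix(coords)
  if (!identical(dim(coords), c(17L, 2L)))
    stop("expected 17 landmarks with (x, y) coordinates")
  if (any(!is.finite(coords))) stop("non-finite landmark coordinates")
  dup <- duplicated(round(coords, 8))
  if (any(dup)) warning("coincident landmarks in specimen ", id)
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, id = as.character(id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s: 17 landmarks, x [%.1f, %.1f], y [%.1f, %.1f]\n",
              x$id, min(x$coords[, 1]), max(x$coords[, 1]),
              min(x$coords[, 2]), max(x$coords[, 2])))
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Draws \code{n_per_class} specimens per class: one masked image and one
#' landmark configuration each, with aligned labels and specimen ids.
#' Per-specimen seeds are derived deterministically from \code{seed}, so the
#' whole dataset is a pure function of \code{(specs, n_per_class, seed)}.
#'
#' @param specs list of \code{\link{class_spec}} objects.
#' @param n_per_class specimens per class (>= 1).
#' @param seed integer root seed.
#' @param canvas image canvas \code{c(height, width)}.
#' @return List with \code{images} (list of \code{masked_image}),
#'   \code{landmarks} (list of \code{landmark_set}), \code{labels}
#'   (character) and \code{ids} (character), all aligned.
#' @export
generate_dataset <- function(specs, n_per_class, seed = 1L,
                             canvas = c(96L, 256L)) {
  if (length(specs) == 0L) stop("specs must be non-empty")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  n <- length(specs) * n_per_class
  images <- vector("list", n); lms <- vector("list", n)
  labels <- character(n); ids <- character(n)
  k <- 0L
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      sub_seed <- (as.integer(seed) * 1000L + k) %% .Machine$integer.max
      id <- sprintf("%s_%03d", spec$label, j)
      images[[k]] <- generate_fish_image(spec, seed = sub_seed,
                                         canvas = canvas)
      lms[[k]] <- generate_landmarks(spec, seed = sub_seed + 500000L, id = id)
      labels[k] <- spec$label
      ids[k] <- id
    }
  }
  list(images = images, landmarks = lms, labels = labels, ids = ids)
}
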