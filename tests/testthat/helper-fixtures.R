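# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# flat two-color spec used across feature tests
two_color_spec <- function(p1 = 0.6, p2 = 0.4, stripes = 0L, noise = 0) {
  class_spec("two", list(list(rgb = c(120, 60, 30), prop = p1),
                         list(rgb = c(30, 60, 200), prop = p2)),
             stripe_count = stripes, color_noise_sd = noise)
}

# masked image whose foreground is an explicit n x 3 pixel list (one row
# per pixel), laid out row-major on a minimal canvas
image_from_pixels <- function(px) {
  n <- nrow(px)
  w <- ceiling(sqrt(n)); h <- ceiling(n / w)
  canvas <- matrix(0L, h, w)
  arr <- array(0L, c(h, w, 3))
  sen <- sentinel_color()
  for (ch in 1:3) {
    plane <- matrix(sen[ch], h, w)
    plane[seq_len(n)] <- px[, ch]
    arr[, , ch] <- plane
  }
  mask <- matrix(FALSE, h, w); mask[seq_len(n)] <- TRUE
  masked_image(arr, mask = mask)
}

# constant-gray image: k intensity levels with given pixel counts
gray_histogram_image <- function(levels, counts) {
  px <- do.call(rbind, lapply(seq_along(levels), function(i)
    matrix(rep(levels[i], counts[i] * 3), ncol = 3, byrow = TRUE)))
  image_from_pixels(px)
}

# 12 disjoint-palette classes, 10 specimens each, with extracted features
disjoint_fixture <- function() cached("disjoint", function() {
  ds <- generate_dataset(default_class_specs(disjoint_palettes = TRUE),
                         n_per_class = 10, seed = 42)
  feats <- extract_feature_table(ds$images, ids = ds$ids)
  ok <- colSums(is.na(feats)) == 0
  list(ds = ds,
       features = feats,
       table = labeled_feature_table(feats[, ok, drop = FALSE], ds$labels))
})

# 6 classes: 3 palettes shared pairwise, body height differing within each
# pair (shape information required to separate pair members)
overlap_specs <- function() {
  base <- list(c(150, 90, 40), c(40, 90, 200), c(60, 160, 70))
  specs <- list()
  for (p in 1:3) for (s in 1:2) {
    b <- base[[p]]
    pal <- list(list(rgb = b, prop = 0.55),
                list(rgb = pmin(255, b + 60), prop = 0.30),
                list(rgb = round(b / 2), prop = 0.15))
    specs[[length(specs) + 1]] <- class_spec(
      label = sprintf("sp%d_%s", p, c("short", "tall")[s]),
      palette = pal, stripe_count = 2L, stripe_orientation = "vertical",
      body_width_px = 180, body_height_px = c(46, 78)[s],
      landmark_noise_sd = 1.5, color_noise_sd = 8)
  }
  specs
}

overlap_fixture <- function() cached("overlap", function() {
  ds <- generate_dataset(overlap_specs(), n_per_class = 12, seed = 11)
  feats <- extract_feature_table(ds$images, ids = ds$ids)
  ok <- colSums(is.na(feats)) == 0
  fit <- gpa(ds$landmarks)
  shapes <- procrustes_coordinates(fit)
  tab48 <- labeled_feature_table(feats[, ok, drop = FALSE], ds$labels)
  list(ds = ds, features = feats, gpa = fit, shapes = shapes,
       table48 = tab48,
       table82 = combine_features(tab48, shapes))
})

# random landmark configuration (17 x 2) with well-spread points
random_config <- function(scale = 10) {
  landmark_set(matrix(stats::runif(34, 0, scale), 17, 2),
               id = "rand")
}

random_similarity <- function(co) {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s <- stats::runif(1, 0.2, 5)
  t <- stats::runif(2, -20, 20)
  sweep(co %*% R * s, 2, -t)
}

# symmetric non-negative random distance matrix with zero diagonal
random_dist <- function(m, labels = paste0("c", seq_len(m))) {
  x <- matrix(stats::runif(m * m), m, m)
  d <- (x + t(x)) / 2
  diag(d) <- 0
  distance_matrix(d, labels)
}
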