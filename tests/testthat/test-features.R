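test_that("quantization returns exact colors and counts when distinct colors <= k", {
  px <- rbind(matrix(rep(c(10L, 20L, 30L), 700), ncol = 3, byrow = TRUE),
              matrix(rep(c(200L, 0L, 50L), 450), ncol = 3, byrow = TRUE),
              matrix(rep(c(0L, 90L, 0L), 150), ncol = 3, byrow = TRUE))
  img <- image_from_pixels(px)
  pal <- quantize_palette(img)
  expect_equal(pal$count[1:3], c(700L, 450L, 150L))
  expect_equal(unlist(pal[1, c("r", "g", "b")]), c(r = 10, g = 20, b = 30))
  expect_equal(unlist(pal[2, c("r", "g", "b")]), c(r = 200, g = 0, b = 50))
  expect_equal(pal$count[4:7], rep(0L, 4))          # padding slots
  expect_equal(sum(pal$count), sum(img$mask))       # conservation
  hsv <- grDevices::rgb2hsv(matrix(c(10, 20, 30), 3), maxColorValue = 255)
  expect_equal(unlist(pal[1, c("h", "s", "v")]),
               c(h = hsv[1], s = hsv[2], v = hsv[3]))
})

test_that("palette and entropy are invariant to foreground pixel position", {
  set.seed(21)
  px <- matrix(sample(0:255, 900 * 3, replace = TRUE), ncol = 3)
  img <- image_from_pixels(px)
  img_shuffled <- image_from_pixels(px[sample(nrow(px)), ])
  expect_equal(quantize_palette(img, seed = 5),
               quantize_palette(img_shuffled, seed = 5))
  expect_equal(entropy(img), entropy(img_shuffled))
})

test_that("palette counts partition the foreground even with clustering", {
  img <- generate_fish_image(two_color_spec(noise = 20), seed = 13)
  pal <- quantize_palette(img, seed = 2)
  expect_equal(sum(pal$count), sum(img$mask))
  expect_true(all(diff(pal$count) <= 0))  # descending
  pal2 <- quantize_palette(img, seed = 2)
  expect_equal(pal, pal2)                 # deterministic under seed
})

test_that("color ratio is first count over second count", {
  px <- rbind(matrix(rep(c(120L, 60L, 30L), 600), ncol = 3, byrow = TRUE),
              matrix(rep(c(30L, 60L, 200L), 500), ncol = 3, byrow = TRUE))
  expect_equal(color_ratio(quantize_palette(image_from_pixels(px))), 1.2)
  eq <- rbind(matrix(rep(c(1L, 2L, 3L), 40), ncol = 3, byrow = TRUE),
              matrix(rep(c(9L, 9L, 9L), 40), ncol = 3, byrow = TRUE))
  expect_equal(color_ratio(quantize_palette(image_from_pixels(eq))), 1)
  solo <- image_from_pixels(matrix(7L, 30, 3))
  expect_error(color_ratio(quantize_palette(solo)), "degenerate palette")
})

test_that("entropy matches direct histogram summation", {
  expect_equal(entropy(gray_histogram_image(100, 50)), 0)
  expect_equal(entropy(gray_histogram_image(c(40, 200), c(32, 32))), 1)
  img <- gray_histogram_image(c(10, 80, 150, 220), c(32, 16, 8, 8))
  expect_equal(entropy(img), 1.75)  # -(1/2 lg 1/2 + 1/4 lg 1/4 + 2/8 lg 1/8)
})

test_that("entropy equals a brute-force per-pixel tally on random images", {
  set.seed(77)
  for (i in 1:200) {
    h <- sample(4:64, 1); w <- sample(4:64, 1)
    v <- sample(0:255, h * w, replace = TRUE)
    img <- image_from_pixels(matrix(rep(v, each = 3), ncol = 3, byrow = TRUE))
    # independent oracle: per-pixel frequency tally
    p <- as.numeric(table(v)) / (h * w)
    expect_equal(entropy(img), -sum(p * log2(p)), tolerance = 1e-12)
    expect_gte(entropy(img), 0)
    expect_lte(entropy(img), 8)
  }
})

test_that("edge count is zero on flat foregrounds and counts boundary pixels", {
  expect_equal(edge_pixel_count(gray_histogram_image(128, 400)), 0)
  px <- array(255L, c(64, 64, 3)); px[, 1:32, ] <- 0L
  img <- masked_image(px)
  e <- canny_edges(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
  expect_gt(sum(e), 0)
  expect_equal(edge_pixel_count(img), sum(e & img$mask) / sum(img$mask))
})

test_that("normalized edge count decreases when the same pattern is upscaled", {
  mk <- function(s) {
    px <- array(255L, c(32 * s, 32 * s, 3)); px[, seq_len(16 * s), ] <- 0L
    masked_image(px)
  }
  expect_gt(edge_pixel_count(mk(1)), edge_pixel_count(mk(2)))
})

test_that("line counts respond to stripe bars and respect rotation", {
  spec <- class_spec("bars",
                     list(list(rgb = c(200, 180, 60), prop = 0.55),
                          list(rgb = c(120, 100, 40), prop = 0.30),
                          list(rgb = c(20, 20, 20), prop = 0.15)),
                     stripe_count = 3, stripe_orientation = "vertical",
                     color_noise_sd = 0)
  img <- generate_fish_image(spec, seed = 4)
  lf <- line_features(img)
  expect_gte(lf[["vertical"]], 6)  # 3 bars -> at least 6 vertical boundaries
  expect_lte(lf[["horizontal"]], 4)
  # rotate the raster 90 degrees: horizontal and vertical swap
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  d <- dim(img$pixels)
  rot <- masked_image(array(c(rot90(img$pixels[, , 1]),
                              rot90(img$pixels[, , 2]),
                              rot90(img$pixels[, , 3])), c(d[2], d[1], 3)),
                      mask = rot90(img$mask))
  lr <- line_features(rot)
  expect_identical(lr[["vertical"]], lf[["horizontal"]])
  expect_identical(lr[["horizontal"]], lf[["vertical"]])
  expect_identical(lr[["diagonal"]], lf[["diagonal"]])
  # constant image has no lines
  expect_identical(unname(line_features(gray_histogram_image(90, 800))),
                   c(0L, 0L, 0L))
})

test_that("the feature vector has the documented 48-element layout", {
  img <- generate_fish_image(two_color_spec(noise = 5), seed = 6)
  fv <- extract_features(img)
  expect_length(fv, 48)
  expect_identical(names(fv), feature_names())
  expect_length(grep("^Color_", names(fv)), 42)
  color_vals <- fv[grep("^Color_", names(fv))]
  expect_true(all(color_vals >= 0 & color_vals <= 1))
})

test_that("features ignore background pixels entirely", {
  img <- generate_fish_image(two_color_spec(noise = 7), seed = 9)
  # re-embed the same foreground in a larger canvas
  d <- dim(img$pixels)
  big <- array(0L, c(d[1] + 20, d[2] + 20, 3))
  sen <- sentinel_color()
  for (ch in 1:3) {
    plane <- matrix(sen[ch], d[1] + 20, d[2] + 20)
    plane[11:(10 + d[1]), 11:(10 + d[2])] <- img$pixels[, , ch]
    big[, , ch] <- plane
  }
  big_img <- masked_image(big)
  expect_equal(extract_features(big_img), extract_features(img))
})

test_that("a degenerate color ratio becomes NA without aborting the vector", {
  img <- image_from_pixels(matrix(99L, 300, 3))
  fv <- extract_features(img)
  expect_true(is.na(fv[["color_ratio"]]))
  expect_length(fv, 48)
  blank <- suppressWarnings(masked_image(
    array(rep(sentinel_color(), each = 16), c(4, 4, 3))))
  expect_error(extract_features(blank), "empty foreground")
})
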