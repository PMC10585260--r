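# Colorimetry and threshold evaluation.

test_that("sRGB -> CIELAB hits the canonical anchor colors", {
  expect_equal(unname(rgb_to_lab(c(255, 255, 255))), c(100, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(rgb_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  # primary green, reference value quoted in any colorimetry table
  expect_equal(unname(rgb_to_lab(c(0, 255, 0))),
               c(87.737, -86.185, 83.181), tolerance = 5e-3)
  # mid green: strongly negative a*, cross-checked against an independent
  # colorimetry implementation (grDevices::convertColor, frozen here)
  expect_equal(unname(rgb_to_lab(c(0, 128, 0))),
               c(46.1694, -51.8574, 49.7897), tolerance = 0.4)
  expect_lt(rgb_to_lab(c(0, 128, 0))[["a"]], -40)
})

test_that("CIELAB agrees with an independent conversion on random pixels", {
  set.seed(42)
  m <- matrix(sample(0:255, 600, replace = TRUE), ncol = 3)
  ref <- grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(rgb_to_lab(m) - ref)), 0.4)
})

test_that("Lab -> sRGB inverse round-trips random pixels within 1/255", {
  set.seed(7)
  m <- matrix(sample(0:255, 3000, replace = TRUE), ncol = 3)
  back <- lab_to_rgb(rgb_to_lab(m))
  expect_lt(max(abs(back - m)), 1)
  expect_lt(stats::median(abs(back - m)), 1e-6)
})

test_that("HSB conversion matches the hexcone transform", {
  expect_equal(unname(rgb_to_hsb(c(255, 0, 0))), c(0, 1, 1))
  expect_equal(unname(rgb_to_hsb(c(0, 0, 255))), c(240, 1, 1))
  grey <- rgb_to_hsb(c(128, 128, 128))
  expect_equal(unname(grey), c(0, 0, 128 / 255), tolerance = 1e-9)
  set.seed(11)
  for (i in 1:50) {
    p <- sample(0:255, 3, replace = TRUE)
    expect_equal(unname(rgb_to_hsb(p)), unname(oracle_hsb(p)),
                 tolerance = 1e-9)
  }
  # raster form maps every pixel
  img <- uniform_image(c(0, 0, 255), 3, 4)
  hs <- rgb_to_hsb(img)
  expect_equal(dim(hs), c(3L, 4L, 3L))
  expect_true(all(hs[, , 1] == 240))
})

test_that("ImageJ 0-255 Lab scale mapping matches its published convention", {
  expect_equal(unname(lab_to_imagej_scale(c(100, 0, 0))), c(255, 128, 128))
  expect_equal(unname(lab_to_imagej_scale(c(0, -128, -128))), c(0, 0, 0))
  # a* = 10 on the CIELAB scale is the familiar ImageJ reverted cutoff 138
  expect_equal(lab_to_imagej_scale(c(50, 10, 0))[["a255"]], 138)
  # clamped at the corners
  expect_equal(lab_to_imagej_scale(c(120, 140, -140))[["a255"]], 255)
})

test_that("channel_interval validates its bounds", {
  expect_error(channel_interval("a", min = 5, max = 2), "min < max")
  expect_error(channel_interval("q", min = 0), "must be one of")
  expect_error(channel_interval("a", min = "x"), "finite numbers")
  # hue wraparound is the one sanctioned min > max case
  expect_s3_class(channel_interval("H", min = 350, max = 10),
                  "channel_interval")
  expect_error(threshold_spec(channel_interval("a", min = 0),
                              channel_interval("a", min = 1)),
               "duplicated")
})

test_that("apply_threshold evaluates conjunctive specs over rasters", {
  # uniform color with a* = 20 passes an a > 16.15 cutoff everywhere
  rgb20 <- lab_to_rgb(c(50, 20, 10))
  img <- uniform_image(rgb20, 5, 7)
  expect_equal(rgb_to_lab(rgb20)[["a"]], 20, tolerance = 1e-9)
  m <- apply_threshold(img, threshold_spec(channel_interval("a", min = 16.15)))
  expect_true(all(m))
  expect_equal(dim(m), c(5L, 7L))
  # pure green board (a* ~ -33) fails background removal at a > -10
  board <- uniform_image(c(60, 120, 60))
  expect_false(any(apply_threshold(
    board, threshold_spec(channel_interval("a", min = -10)))))
  # full-range spec accepts everything, with a warning
  expect_warning(m_all <- apply_threshold(board, threshold_spec()),
                 "full range")
  expect_true(all(m_all))
})

test_that("strict and inclusive bounds differ exactly at the boundary", {
  img <- uniform_image(c(50, 50, 50))
  v <- unclass(img)[1, 1, 1]  # R channel value 50
  at <- function(iv) all(apply_threshold(img, threshold_spec(iv)))
  expect_false(at(channel_interval("R", min = v, min_strict = TRUE)))
  expect_true(at(channel_interval("R", min = v, min_strict = FALSE)))
  expect_false(at(channel_interval("R", max = v, max_strict = TRUE)))
  expect_true(at(channel_interval("R", max = v, max_strict = FALSE)))
})

test_that("hue wraparound interval selects colors across 0 degrees", {
  red <- uniform_image(c(255, 0, 0))       # h = 0
  orange <- uniform_image(c(255, 128, 0))  # h = 30
  cyan <- uniform_image(c(0, 255, 255))    # h = 180
  spec <- threshold_spec(channel_interval("H", min = 350, max = 10))
  expect_true(all(apply_threshold(red, spec)))
  expect_false(any(apply_threshold(orange, spec)))
  expect_false(any(apply_threshold(cyan, spec)))
})

test_that("conjunctive masks equal the intersection of per-channel masks", {
  set.seed(3)
  px <- array(sample(0:255, 64 * 64 * 3, replace = TRUE),
              dim = c(64, 64, 3))
  img <- image_rgb(px)
  ivs <- list(channel_interval("a", min = -5, max = 30),
              channel_interval("V", min = 0.15),
              channel_interval("G", max = 200))
  joint <- apply_threshold(img, threshold_spec(ivs))
  singles <- lapply(ivs, function(iv)
    apply_threshold(img, threshold_spec(iv)))
  expect_identical(joint, singles[[1]] & singles[[2]] & singles[[3]])
})

test_that("tightening an interval never adds pixels to the mask", {
  set.seed(5)
  px <- array(sample(0:255, 48 * 48 * 3, replace = TRUE), dim = c(48, 48, 3))
  img <- image_rgb(px)
  for (lo in c(-20, -5, 5, 15)) {
    wide <- apply_threshold(img, threshold_spec(channel_interval("a", min = lo)))
    tight <- apply_threshold(img,
                             threshold_spec(channel_interval("a", min = lo + 5)))
    expect_true(all(wide | !tight))  # tight subset of wide
  }
})
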