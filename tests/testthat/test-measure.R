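# Calibration, per-object measurement, fractions, color profiles.

block_labels <- function(h, w, blocks, min_area = 1) {
  m <- matrix(FALSE, h, w)
  for (b in blocks) m[b[1]:b[2], b[3]:b[4]] <- TRUE
  label_objects(m, min_area)
}

test_that("calibrate_scale derives mm/px and covaries with downsizing", {
  expect_equal(calibrate_scale(50, 200)$mm_per_px, 0.25)
  # the same reference measured on the original image, after 2x downsize
  expect_equal(calibrate_scale(50, 200, downsize_scale = 0.5)$mm_per_px, 0.5)
  expect_error(calibrate_scale(50, 0), "positive")
  expect_error(calibrate_scale(-1, 10), "positive")
})

test_that("object length is the vertical extent, width the horizontal", {
  lo <- block_labels(500, 500, list(c(101, 400, 201, 350)))
  cal <- calibrate_scale(1, 10)  # 0.1 mm per px
  m <- measure_object(lo, 1, cal)
  expect_equal(m$length_mm, 30.0)
  expect_equal(m$width_mm, 15.0)
  expect_equal(m$area_mm2, 300 * 150 * 0.01)
  # rotating the object by 90 degrees swaps the two: orientation matters
  lo_t <- block_labels(500, 500, list(c(201, 350, 101, 400)))
  m_t <- measure_object(lo_t, 1, cal)
  expect_equal(m_t$length_mm, 15.0)
  expect_equal(m_t$width_mm, 30.0)
  # a single pixel has inclusive extent 1 (nonzero size)
  lo1 <- block_labels(10, 10, list(c(5, 5, 5, 5)))
  m1 <- measure_object(lo1, 1, cal)
  expect_equal(m1$length_mm, 0.1)
  expect_equal(m1$width_mm, 0.1)
})

test_that("major-axis mode measures along the principal direction", {
  # a diagonal line: bbox extent underestimates its true length
  m <- matrix(FALSE, 60, 60)
  for (i in 1:40) m[10 + i, 10 + i] <- TRUE
  lo <- label_objects(m, 1)
  bbox <- measure_objects(lo, length_mode = "bbox")
  maj <- measure_objects(lo, length_mode = "major_axis")
  expect_equal(bbox$length_px, 40)
  expect_gt(maj$length_px, 50)  # ~ 40 * sqrt(2)
})

test_that("border and merged-object flags fire where intended", {
  lo <- block_labels(100, 100,
                     list(c(1, 10, 20, 29),      # touches top border
                          c(40, 49, 20, 29),     # interior, 100 px
                          c(60, 100, 40, 95)))   # huge -> merged suspect
  m <- measure_objects(lo)
  expect_equal(m$touches_border, c(TRUE, FALSE, TRUE))
  expect_equal(m$merged_suspect, c(FALSE, FALSE, TRUE))
})

test_that("feature fractions count pixels per image and per object", {
  fruit <- matrix(FALSE, 50, 50)
  fruit[1:20, 1:50] <- TRUE    # 1000 fruit pixels
  feature <- matrix(FALSE, 50, 50)
  feature[1:5, 1:50] <- TRUE   # 250 feature pixels
  expect_equal(feature_fraction(fruit, feature)$image_pct, 25.0)
  expect_equal(feature_fraction(fruit, matrix(FALSE, 50, 50))$image_pct, 0)
  expect_error(feature_fraction(feature, fruit), "subset")
  expect_warning(
    z <- feature_fraction(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
    "empty fruit mask")
  expect_equal(z$image_pct, 0)
})

test_that("per-object fractions match brute-force counts", {
  set.seed(9)
  fruit <- matrix(FALSE, 60, 60)
  fruit[5:24, 5:24] <- TRUE
  fruit[35:54, 30:59] <- TRUE
  feature <- fruit & random_mask(60, 60, 0.3)
  lo <- label_objects(fruit, 1)
  ff <- feature_fraction(fruit, feature, lo)
  for (k in 1:2) {
    ink <- lo$labels == k
    expect_equal(ff$object_pct[k], 100 * sum(feature & ink) / sum(ink))
  }
  # feature pixels partition across objects: totals agree
  expect_equal(sum(ff$object_pct / 100 * lo$objects$n_pixels),
               sum(feature))
})

test_that("color profile nails an exact chart color and orders by luminance", {
  chart <- color_chart()
  gp <- chart[chart$name == "Greyed-Purple 185-A", ]
  expect_equal(unlist(gp[c("L", "a", "b")], use.names = FALSE),
               c(34.4, 42.0, 12.7))
  # a uniform patch built from that Lab triple matches it at distance ~0
  patch <- image_rgb(array(rep(lab_to_rgb(c(34.4, 42.0, 12.7)),
                               each = 36), dim = c(6, 6, 3)))
  pr <- color_profile(patch, matrix(TRUE, 6, 6))
  expect_equal(pr$matches$name, rep("Greyed-Purple 185-A", 3))
  expect_lt(max(pr$matches$distance), 1e-6)
  # single-pixel feature: min = median = max
  img <- uniform_image(c(10, 10, 10), 4, 4)
  px <- unclass(img); px[2, 3, ] <- c(150, 40, 40)
  img <- image_rgb(px)
  feat <- matrix(FALSE, 4, 4); feat[2, 3] <- TRUE
  pr1 <- color_profile(img, feat)
  expect_equal(pr1$min_rgb, c(150, 40, 40))
  expect_equal(pr1$max_rgb, c(150, 40, 40))
  expect_equal(pr1$median_rgb, c(150, 40, 40))
  # dark and bright pixels sort by luminance into min/max
  feat2 <- matrix(FALSE, 4, 4); feat2[1, 1] <- TRUE; feat2[2, 3] <- TRUE
  px[1, 1, ] <- c(240, 240, 240)
  pr2 <- color_profile(image_rgb(px), feat2)
  expect_equal(pr2$min_rgb, c(150, 40, 40))
  expect_equal(pr2$max_rgb, c(240, 240, 240))
})

test_that("empty feature regions yield an unavailable profile, not an error", {
  img <- uniform_image(c(60, 120, 60))
  pr <- color_profile(img, matrix(FALSE, 8, 8))
  expect_false(pr$available)
  expect_null(pr$matches)
})

test_that("nearest chart matching equals exhaustive search", {
  chart <- color_chart()
  ref <- as.matrix(chart[c("L", "a", "b")])
  set.seed(17)
  for (i in 1:100) {
    p <- sample(0:255, 3, replace = TRUE)
    lab <- rgb_to_lab(p)
    d <- sqrt(colSums((t(ref) - lab)^2))
    nn <- fruitpix:::nearest_chart_color(matrix(lab, 1), chart)
    expect_equal(nn$name, chart$name[which.min(d)])
    expect_equal(nn$distance, min(d), tolerance = 1e-9)
  }
})
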