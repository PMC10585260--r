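# Configuration round-trips and batch orchestration.

year_config_path <- function(year) {
  system.file("extdata", "configs",
              sprintf("blackberry_rdr_%d.yaml", year),
              package = "fruitpix", mustWork = TRUE)
}

test_that("bundled campaign configs load with their cutoffs intact", {
  cfg19 <- load_config(year_config_path(2019))
  expect_equal(cfg19$background[[1]]$min, -10)
  expect_equal(cfg19$features$RDR[[1]]$min, 7.51)
  cfg21 <- load_config(year_config_path(2021))
  expect_equal(cfg21$background[[1]]$min, -8.5)
  expect_equal(cfg21$features$RDR[[1]]$min, 8.58)
  # unconstrained channels (full range): only a* carries an interval
  sp <- build_specs(cfg19)
  expect_length(sp$background$intervals, 1L)
  expect_equal(sp$background$intervals[[1]]$channel, "a")
  expect_true(sp$background$intervals[[1]]$min_strict)
  expect_null(sp$background$intervals[[1]]$max)
})

test_that("unknown configuration keys are rejected, all listed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_dim: 1500", "bogus_key: 1", "another_bad: x",
               "features:", "  RDR:",
               "  - {space: lab, channel: a, min: 5}"), path)
  err <- tryCatch(load_config(path), error = conditionMessage)
  expect_match(err, "bogus_key")
  expect_match(err, "another_bad")
})

test_that("size traits without a calibration fail validation upfront", {
  expect_error(pipeline_config(calibration = NULL,
                               traits = c("length", "feature_pct")),
               "no calibration")
  # fine without size traits
  expect_s3_class(pipeline_config(calibration = NULL,
                                  traits = "feature_pct"),
                  "pipeline_config")
})

test_that("configs round-trip through YAML serialization identically", {
  for (year in c(2019, 2020, 2021)) {
    cfg <- load_config(year_config_path(year))
    path <- withr::local_tempfile(fileext = ".yaml")
    write_config(cfg, path)
    expect_identical(load_config(path), cfg)
  }
})

test_that("ImageJ-scale Lab thresholds are converted at spec build time", {
  cfg <- pipeline_config(
    lab_scale = "imagej",
    background = list(list(space = "lab", channel = "a", min = 110)),
    features = list(RDR = list(list(space = "lab", channel = "a",
                                    min = 138))),
    traits = "feature_pct")
  sp <- build_specs(cfg)
  expect_equal(sp$background$intervals[[1]]$min, 110 - 128)
  expect_equal(sp$features$RDR$intervals[[1]]$min, 10)
})

test_that("process_image recovers a three-berry scene end to end", {
  spec <- scene_spec(reverted_fraction = 0.3, seed = 7, n_specks = 0)
  sc <- render_scene(spec)
  cfg <- scene_analysis_config(spec, despeckle_radius = 0,
                               feature_despeckle_radius = 0)
  res <- process_image(sc$image, cfg, image_id = "scene7")
  objs <- res[!is.na(res$object_label), ]
  expect_equal(nrow(objs), 3L)
  expect_equal(unique(objs$status), "ok")
  tr <- sc$truth
  expect_equal(objs$length_mm,
               (tr$berries$max_row - tr$berries$min_row + 1) * tr$mm_per_px)
  expect_equal(objs$RDR_pct,
               100 * tr$berries$reverted_px / tr$berries$n_pixels)
  smry <- res[is.na(res$object_label), ]
  expect_equal(smry$n_pixels, tr$fruit_px)
  expect_equal(smry$RDR_pct, 100 * tr$fraction)
  expect_match(smry$color_median_name, "^(Red|Greyed-Red|Dark-Red)")
})

test_that("an all-background image yields a zero-object summary row", {
  img <- uniform_image(c(60, 120, 60), 40, 40)
  cfg <- pipeline_config(normalize = FALSE, sharpen_amount = 0,
                         denoise_radius = 0, traits = "feature_pct")
  res <- process_image(img, cfg, image_id = "empty")
  expect_equal(nrow(res), 1L)
  expect_equal(res$status, "empty_segmentation")
  expect_true(is.na(res$object_label))
  expect_equal(res$RDR_pct, 0)
})

test_that("undecodable files become error rows and the batch continues", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(seed = 1, n_specks = 0)
  write_image_rgb(render_scene(spec)$image, file.path(dir, "a_good.png"))
  writeLines("not an image", file.path(dir, "b_corrupt.jpg"))
  cfg <- scene_analysis_config(spec)
  out <- withr::local_tempfile(fileext = ".csv")
  res <- process_batch(dir, cfg, out)
  expect_equal(attr(res, "n_errors"), 1L)
  expect_true("decode_error" %in% res$status)
  expect_true(any(res$status == "ok"))
  expect_error(process_batch(withr::local_tempdir(), cfg, out), "no images")
})

test_that("batches are processed in filename order with a stable schema", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(seed = 1, n_specks = 2)
  for (nm in c("c_scene", "a_scene", "b_scene"))
    write_image_rgb(render_scene(
      scene_spec(seed = match(nm, c("a_scene", "b_scene", "c_scene")),
                 n_specks = 2))$image,
      file.path(dir, paste0(nm, ".png")))
  cfg <- scene_analysis_config(spec)
  out <- file.path(dir, "results.csv")
  res <- process_batch(dir, cfg, out)
  expect_equal(unique(res$image_id), c("a_scene", "b_scene", "c_scene"))
  expect_identical(names(res),
                   c("image_id", "object_label", "n_pixels", "length_mm",
                     "width_mm", "area_mm2", "RDR_pct", "color_min_name",
                     "color_median_name", "color_max_name", "flags",
                     "status"))
  expect_true(file.exists(file.path(dir, "settings.json")))
})

test_that("re-running a batch and replaying its sidecar reproduce the CSV", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(seed = 4, n_specks = 3, anti_alias = TRUE)
  for (i in 1:2)
    write_image_rgb(render_scene(scene_spec(seed = i, n_specks = 3,
                                            anti_alias = TRUE))$image,
                    file.path(dir, sprintf("scene_%d.png", i)))
  cfg <- scene_analysis_config(spec)
  out1 <- file.path(dir, "r1.csv"); out2 <- file.path(dir, "r2.csv")
  process_batch(dir, cfg, out1, settings_json = file.path(dir, "s1.json"))
  process_batch(dir, cfg, out2, settings_json = file.path(dir, "s2.json"))
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
  # settings sidecar replay: identical configuration, identical results
  cfg_replay <- settings_to_config(file.path(dir, "s1.json"))
  expect_identical(cfg_replay, cfg)
  out3 <- file.path(dir, "r3.csv")
  process_batch(dir, cfg_replay, out3,
                settings_json = file.path(dir, "s3.json"))
  expect_identical(readLines(out1), readLines(out3))
})
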