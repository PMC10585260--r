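#' Batch orchestration and results output
#'
#' Runs the full pipeline (preprocess, background removal, feature
#' detection, labeling, measurement) over single images or whole
#' directories, collecting one tabular results file plus a JSON settings
#' sidecar that echoes the exact configuration for repeatability.
#' Analysis is fully deterministic: identical input and configuration
#' produce byte-identical results.
#'
#' @name batch
NULL

results_schema <- function(feature_names) {
  c("image_id", "object_label", "n_pixels",
    "length_mm", "width_mm", "area_mm2",
    paste0(feature_names, "_pct"),
    "color_min_name", "color_median_name", "color_max_name",
    "flags", "status")
}

empty_results_row <- function(image_id, feature_names, status,
                              n_pixels = 0L) {
  row <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(feature_names)),
    paste0(feature_names, "_pct"))))
  cbind(data.frame(image_id = image_id, object_label = NA_integer_,
                   n_pixels = n_pixels, length_mm = NA_real_,
                   width_mm = NA_real_, area_mm2 = NA_real_),
        row,
        data.frame(color_min_name = NA_character_,
                   color_median_name = NA_character_,
                   color_max_name = NA_character_,
                   flags = "", status = status,
                   stringsAsFactors = FALSE))
}

#' Process a single image through the pipeline
#'
#' Decoding or processing failures are captured as a `decode_error` /
#' `error` status row rather than raised, so a batch never aborts on one
#' bad file. Output rows are: one row per detected fruit object, then one
#' per-image summary row (`object_label` `NA`) carrying the whole-image
#' feature fraction and total fruit pixel count.
#'
#' @param input an image path, or an [image_rgb()] raster.
#' @param cfg a [pipeline_config()].
#' @param image_id identifier for the output rows (default: file name
#'   without extension, or `"image"` for in-memory rasters).
#' @param save_masks optional directory; if given, fruit/feature overlay
#'   images are written there for visual quality checking.
#' @return data frame of results rows (see [process_batch()] for the
#'   column schema), with the masks attached as attributes `fruit_mask`
#'   and `feature_masks` for programmatic use.
#' @export
process_image <- function(input, cfg, image_id = NULL, save_masks = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  feature_names <- names(cfg$features)
  if (is.character(input)) {
    if (is.null(image_id))
      image_id <- tools::file_path_sans_ext(basename(input))
    img <- tryCatch(read_image_rgb(input), error = function(e) e)
    if (inherits(img, "error"))
      return(empty_results_row(image_id, feature_names, "decode_error"))
  } else {
    img <- input
    if (is.null(image_id)) image_id <- "image"
  }
  res <- tryCatch(
    process_image_impl(img, cfg, image_id, save_masks),
    error = function(e) {
      warning("processing failed for ", image_id, ": ",
              conditionMessage(e), call. = FALSE)
      empty_results_row(image_id, feature_names, "error")
    })
  res
}

process_image_impl <- function(img, cfg, image_id, save_masks) {
  feature_names <- names(cfg$features)
  specs <- build_specs(cfg)
  img <- preprocess_image(img, max_dim = cfg$max_dim,
                          normalize = cfg$normalize,
                          sharpen_amount = cfg$sharpen_amount,
                          denoise_radius = cfg$denoise_radius)
  region <- if (is.null(cfg$exclude_region)) NULL else
    do.call(crop_region, cfg$exclude_region)
  excl <- exclusion_mask(dim(img)[1:2], region)

  cal <- NULL
  if (!is.null(cfg$calibration)) {
    explicit <- cfg$calibration$downsize_scale
    cal <- calibrate_scale(cfg$calibration$reference_length_mm,
                           cfg$calibration$reference_px,
                           downsize_scale = explicit %||%
                             (attr(img, "scale_factor") %||% 1))
  }

  fruit <- withCallingHandlers(
    remove_background(img, specs$background, cfg$despeckle_radius, excl),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!any(fruit)) {
    out <- empty_results_row(image_id, feature_names, "empty_segmentation")
    if ("feature_pct" %in% cfg$traits)
      out[paste0(feature_names, "_pct")] <- 0
    attr(out, "fruit_mask") <- fruit
    return(out)
  }
  objects <- label_objects(fruit, cfg$min_object_area)
  feats <- lapply(specs$features, function(sp)
    detect_feature(img, fruit, sp, cfg$feature_despeckle_radius))
  fracs <- lapply(feats, function(fm) feature_fraction(fruit, fm, objects))

  want <- function(tr) tr %in% cfg$traits
  meas <- measure_objects(objects, cal, length_mode = cfg$length_mode)

  n <- objects$n_objects
  obj_rows <- data.frame(image_id = rep(image_id, n),
                         object_label = meas$label,
                         n_pixels = meas$n_pixels,
                         length_mm = if (want("length")) meas$length_mm
                                     else NA_real_,
                         width_mm = if (want("width")) meas$width_mm
                                    else NA_real_,
                         area_mm2 = if (want("area")) meas$area_mm2
                                    else NA_real_)
  for (fn in feature_names)
    obj_rows[[paste0(fn, "_pct")]] <-
      if (want("feature_pct")) fracs[[fn]]$object_pct else NA_real_

  profile_names <- function(mask) {
    if (!want("color_profile") || !any(mask))
      return(c(NA_character_, NA_character_, NA_character_))
    pr <- color_profile(img, mask)
    pr$matches$name
  }
  first_feat <- feats[[1L]]
  obj_prof <- t(vapply(seq_len(n), function(k)
    profile_names(first_feat & objects$labels == k), character(3L)))
  obj_rows$color_min_name <- obj_prof[, 1L]
  obj_rows$color_median_name <- obj_prof[, 2L]
  obj_rows$color_max_name <- obj_prof[, 3L]
  obj_rows$flags <- apply(cbind(ifelse(meas$merged_suspect,
                                       "merged_suspect", ""),
                                ifelse(meas$touches_border,
                                       "touches_border", "")),
                          1L, function(x)
                            paste(x[nzchar(x)], collapse = ";"))
  obj_rows$status <- rep("ok", n)

  summary_row <- empty_results_row(image_id, feature_names, "ok",
                                   n_pixels = sum(fruit))
  for (fn in feature_names)
    summary_row[[paste0(fn, "_pct")]] <-
      if (want("feature_pct")) fracs[[fn]]$image_pct else NA_real_
  img_prof <- profile_names(first_feat)
  summary_row$color_min_name <- img_prof[1L]
  summary_row$color_median_name <- img_prof[2L]
  summary_row$color_max_name <- img_prof[3L]

  out <- rbind(obj_rows, summary_row)
  rownames(out) <- NULL
  if (!is.null(save_masks)) {
    dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
    write_mask_image(fruit,
                     file.path(save_masks, paste0(image_id, "_masks.png")),
                     feature = first_feat)
  }
  attr(out, "fruit_mask") <- fruit
  attr(out, "feature_masks") <- feats
  out
}

#' Process a directory of images and write results
#'
#' Images (`.jpg`, `.jpeg`, `.png`, case-insensitive) are processed in
#' lexicographic filename order under one uniform configuration. Writes
#' the results CSV and a JSON settings sidecar echoing the exact
#' configuration plus the tool version. Per-image failures become status
#' rows; the batch always completes.
#'
#' CSV columns: `image_id`, `object_label` (`NA` on per-image summary
#' rows), `n_pixels`, `length_mm`, `width_mm`, `area_mm2`, one
#' `<feature>_pct` column per configured feature, `color_min_name`,
#' `color_median_name`, `color_max_name`, `flags`
#' (`merged_suspect`/`touches_border`), `status` (`ok`,
#' `empty_segmentation`, `decode_error`, `error`).
#'
#' @param input_dir directory of images.
#' @param cfg a [pipeline_config()].
#' @param output_csv results CSV path.
#' @param settings_json settings sidecar path (default: `settings.json`
#'   next to the CSV).
#' @param save_masks optional directory for overlay images.
#' @return the results data frame, invisibly, with attribute `n_errors`
#'   (number of images whose status is an error).
#' @export
process_batch <- function(input_dir, cfg, output_csv,
                          settings_json = NULL, save_masks = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(input_dir))
    stop("input directory not found: ", input_dir, call. = FALSE)
  files <- list.files(input_dir, pattern = "\\.(jpe?g|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("no images found in ", input_dir, call. = FALSE)
  files <- files[order(basename(files), method = "radix")]
  rows <- lapply(files, function(f) {
    r <- process_image(f, cfg, save_masks = save_masks)
    attr(r, "fruit_mask") <- NULL
    attr(r, "feature_masks") <- NULL
    r
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  utils::write.csv(results, output_csv, row.names = FALSE, na = "")
  if (is.null(settings_json))
    settings_json <- file.path(dirname(output_csv), "settings.json")
  cfg_list <- unclass(cfg)
  cfg_list <- cfg_list[!vapply(cfg_list, is.null, logical(1L))]
  jsonlite::write_json(list(tool = "fruitpix",
                            version = cfg$version,
                            n_images = length(files),
                            config = cfg_list),
                       settings_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  err_status <- c("decode_error", "error")
  n_err <- length(unique(results$image_id[results$status %in% err_status]))
  attr(results, "n_errors") <- n_err
  invisible(results)
}
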