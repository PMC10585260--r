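#' Pipeline configuration
#'
#' All analysis settings live in a single validated configuration object,
#' serializable to YAML (and echoed to a JSON sidecar next to every
#' results file) so any run can be reproduced exactly from its recorded
#' settings.
#'
#' @name config
NULL

.CONFIG_KEYS <- c("max_dim", "normalize", "sharpen_amount", "denoise_radius",
                  "exclude_region", "lab_scale", "background", "features",
                  "despeckle_radius", "feature_despeckle_radius",
                  "min_object_area", "calibration", "traits", "length_mode",
                  "random_seed", "version")
.INTERVAL_KEYS <- c("space", "channel", "min", "max",
                    "min_strict", "max_strict")
.TRAITS <- c("length", "width", "area", "feature_pct", "color_profile")
.SIZE_TRAITS <- c("length", "width", "area")

# unwrap length-1 lists coming from JSON/YAML parsers
scal <- function(x) if (is.list(x) && length(x) == 1L) x[[1L]] else x

num_or_null <- function(x) {
  x <- scal(x)
  if (is.null(x)) NULL else as.numeric(x)
}

#' Construct and validate a pipeline configuration
#'
#' Threshold entries are lists like
#' `list(space = "lab", channel = "a", min = 7.51)`; omitted channels are
#' full range, omitted bounds are open, and bounds are strict (`>`)
#' unless `min_strict`/`max_strict` is `FALSE`. With
#' `lab_scale = "imagej"`, Lab-space bounds are interpreted on ImageJ's
#' 0--255 scale (see [lab_to_imagej_scale()]) and converted at use time.
#'
#' @param max_dim downsizing bound (default 1500).
#' @param normalize apply full-range contrast normalization?
#' @param sharpen_amount,denoise_radius enhancement settings
#'   (see [enhance()]); set both to 0 to disable pre-processing.
#' @param exclude_region optional `list(top, left, bottom, right)`
#'   fractional crop region flagged ineligible (e.g. around the size
#'   reference).
#' @param lab_scale `"cielab"` (default) or `"imagej"`.
#' @param background list of threshold entries selecting *fruit* pixels.
#' @param features named list (feature name -> list of threshold
#'   entries), e.g. `list(RDR = list(list(space = "lab", channel = "a",
#'   min = 7.51)))`.
#' @param despeckle_radius opening radius for the fruit mask.
#' @param feature_despeckle_radius opening radius for feature masks.
#' @param min_object_area minimum labeled-object pixel count.
#' @param calibration optional `list(reference_length_mm, reference_px)`;
#'   required when any size trait is requested.
#' @param traits traits to include in the output (subset of
#'   `length, width, area, feature_pct, color_profile`).
#' @param length_mode `"bbox"` (vertical/horizontal extent) or
#'   `"major_axis"`.
#' @param random_seed optional seed recorded for fixture generation
#'   (analysis itself is deterministic and never consumes randomness).
#' @param version tool version string (filled automatically).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_dim = 1500, normalize = TRUE,
                            sharpen_amount = 1, denoise_radius = 1,
                            exclude_region = NULL, lab_scale = "cielab",
                            background = list(list(space = "lab",
                                                   channel = "a",
                                                   min = -10)),
                            features = list(RDR = list(list(space = "lab",
                                                            channel = "a",
                                                            min = 7.51))),
                            despeckle_radius = 2,
                            feature_despeckle_radius = 1,
                            min_object_area = 50, calibration = NULL,
                            traits = c("length", "width", "area",
                                       "feature_pct", "color_profile"),
                            length_mode = "bbox", random_seed = NULL,
                            version = NULL) {
  problems <- character()
  cfg <- list(
    max_dim = as.numeric(scal(max_dim)),
    normalize = isTRUE(scal(normalize)),
    sharpen_amount = as.numeric(scal(sharpen_amount)),
    denoise_radius = as.numeric(scal(denoise_radius)),
    exclude_region = normalize_region(exclude_region),
    lab_scale = as.character(scal(lab_scale)),
    background = normalize_intervals(background, "background"),
    features = normalize_features(features),
    despeckle_radius = as.numeric(scal(despeckle_radius)),
    feature_despeckle_radius = as.numeric(scal(feature_despeckle_radius)),
    min_object_area = as.numeric(scal(min_object_area)),
    calibration = normalize_calibration(calibration),
    traits = as.character(unlist(traits)),
    length_mode = as.character(scal(length_mode)),
    random_seed = num_or_null(random_seed),
    version = as.character(scal(version) %||%
                             utils::packageVersion("fruitpix")))
  if (cfg$max_dim < 1) problems <- c(problems, "max_dim must be >= 1")
  if (cfg$sharpen_amount < 0)
    problems <- c(problems, "sharpen_amount must be >= 0")
  if (cfg$denoise_radius < 0)
    problems <- c(problems, "denoise_radius must be >= 0")
  if (!cfg$lab_scale %in% c("cielab", "imagej"))
    problems <- c(problems, "lab_scale must be 'cielab' or 'imagej'")
  if (cfg$despeckle_radius < 0 || cfg$feature_despeckle_radius < 0)
    problems <- c(problems, "despeckle radii must be >= 0")
  if (cfg$min_object_area < 1)
    problems <- c(problems, "min_object_area must be >= 1")
  bad_traits <- setdiff(cfg$traits, .TRAITS)
  if (length(bad_traits) > 0L)
    problems <- c(problems, paste0("unknown traits: ",
                                   paste(bad_traits, collapse = ", ")))
  if (!cfg$length_mode %in% c("bbox", "major_axis"))
    problems <- c(problems, "length_mode must be 'bbox' or 'major_axis'")
  if (any(cfg$traits %in% .SIZE_TRAITS) && is.null(cfg$calibration))
    problems <- c(problems,
                  paste0("size traits (",
                         paste(intersect(cfg$traits, .SIZE_TRAITS),
                               collapse = ", "),
                         ") requested but no calibration configured"))
  if (length(cfg$features) == 0L)
    problems <- c(problems, "at least one named feature is required")
  if (length(problems) > 0L)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  # exercise threshold construction now so bad intervals fail before any
  # image is touched
  build_specs(structure(cfg, class = "pipeline_config"))
  structure(cfg, class = "pipeline_config")
}

normalize_region <- function(region) {
  if (is.null(region)) return(NULL)
  extra <- setdiff(names(region), c("top", "left", "bottom", "right"))
  if (length(extra) > 0L)
    stop("invalid configuration:\n  - unknown exclude_region keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  region <- lapply(region, function(v) as.numeric(scal(v)))
  # validates bounds
  crop_region(region$top, region$left, region$bottom, region$right)
  region[c("top", "left", "bottom", "right")]
}

normalize_calibration <- function(cal) {
  if (is.null(cal)) return(NULL)
  known <- c("reference_length_mm", "reference_px", "downsize_scale")
  extra <- setdiff(names(cal), known)
  if (length(extra) > 0L)
    stop("invalid configuration:\n  - unknown calibration keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  out <- list(reference_length_mm = num_or_null(cal$reference_length_mm),
              reference_px = num_or_null(cal$reference_px))
  if (!is.null(cal$downsize_scale))
    out$downsize_scale <- num_or_null(cal$downsize_scale)
  if (is.null(out$reference_length_mm) || is.null(out$reference_px))
    stop("invalid configuration:\n  - calibration requires ",
         "reference_length_mm and reference_px", call. = FALSE)
  out
}

normalize_intervals <- function(lst, where) {
  if (is.null(lst)) return(list())
  if (!is.list(lst)) stop("invalid configuration:\n  - ", where,
                          " must be a list of threshold entries",
                          call. = FALSE)
  lapply(lst, function(e) {
    extra <- setdiff(names(e), .INTERVAL_KEYS)
    if (length(extra) > 0L)
      stop("invalid configuration:\n  - unknown threshold keys in ", where,
           ": ", paste(extra, collapse = ", "), call. = FALSE)
    if (is.null(e$space) || is.null(e$channel))
      stop("invalid configuration:\n  - threshold entries in ", where,
           " require 'space' and 'channel'", call. = FALSE)
    out <- list(space = as.character(scal(e$space)),
                channel = as.character(scal(e$channel)))
    if (!is.null(e$min)) out$min <- as.numeric(scal(e$min))
    if (!is.null(e$max)) out$max <- as.numeric(scal(e$max))
    if (!is.null(e$min_strict)) out$min_strict <- isTRUE(scal(e$min_strict))
    if (!is.null(e$max_strict)) out$max_strict <- isTRUE(scal(e$max_strict))
    out
  })
}

normalize_features <- function(features) {
  if (is.null(features) || length(features) == 0L) return(list())
  nm <- names(features)
  if (is.null(nm) || any(nm == ""))
    stop("invalid configuration:\n  - every feature must be named",
         call. = FALSE)
  out <- lapply(seq_along(features), function(i)
    normalize_intervals(features[[i]], paste0("feature '", nm[i], "'")))
  names(out) <- nm
  out
}

config_channel <- function(space, channel) {
  space <- tolower(space)
  ch <- switch(space,
               rgb = toupper(channel),
               hsb = , hsv = toupper(channel),
               lab = if (tolower(channel) == "l") "L" else tolower(channel),
               stop("unknown colorspace '", space, "'", call. = FALSE))
  hsb_map <- c(H = "H", S = "S", B = "V", V = "V")
  if (space %in% c("hsb", "hsv")) {
    if (!ch %in% names(hsb_map))
      stop("unknown HSB channel '", channel, "'", call. = FALSE)
    ch <- hsb_map[[ch]]
  }
  if (!ch %in% CHANNELS)
    stop("unknown channel '", channel, "' for space '", space, "'",
         call. = FALSE)
  ch
}

config_interval <- function(e, lab_scale = "cielab") {
  ch <- config_channel(e$space, e$channel)
  mn <- e$min; mx <- e$max
  if (identical(tolower(e$space), "lab") && lab_scale == "imagej") {
    if (!is.null(mn)) mn <- imagej_scale_to_lab_bound(ch, mn)
    if (!is.null(mx)) mx <- imagej_scale_to_lab_bound(ch, mx)
  }
  channel_interval(ch, min = mn, max = mx,
                   min_strict = e$min_strict %||% TRUE,
                   max_strict = e$max_strict %||% TRUE)
}

#' Build runtime threshold specs from a configuration
#'
#' @param cfg a [pipeline_config()].
#' @return list with `background` (a [threshold_spec()]) and `features`
#'   (named list of threshold specs).
#' @export
build_specs <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  list(background = threshold_spec(lapply(cfg$background, config_interval,
                                          lab_scale = cfg$lab_scale)),
       features = lapply(cfg$features, function(f)
         threshold_spec(lapply(f, config_interval,
                               lab_scale = cfg$lab_scale))))
}

#' Load a configuration from YAML
#'
#' Unknown keys are rejected with a message listing every offending key.
#'
#' @param path YAML file path.
#' @return a validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

config_from_list <- function(raw) {
  if (!is.list(raw)) stop("configuration must be a mapping", call. = FALSE)
  extra <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(extra) > 0L)
    stop("invalid configuration:\n  - unknown keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

#' Serialize a configuration to YAML
#'
#' Writing and re-loading a configuration yields an identical object
#' (lossless round trip).
#'
#' @param cfg a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst <- lst[!vapply(lst, is.null, logical(1L))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Rebuild a configuration from a results settings sidecar
#'
#' The JSON sidecar written by [process_batch()] echoes the exact
#' configuration; this reads it back so a run can be replayed.
#'
#' @param path path to a `settings.json` sidecar.
#' @return a validated [pipeline_config()].
#' @export
settings_to_config <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(side$config)) stop("no 'config' entry in ", path, call. = FALSE)
  config_from_list(side$config)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> fruitpix", x$version, "\n")
  cat(sprintf("  preprocess: max_dim %g, normalize %s, sharpen %g, denoise %g\n",
              x$max_dim, x$normalize, x$sharpen_amount, x$denoise_radius))
  fmt_iv <- function(e) {
    b <- character()
    if (!is.null(e$min)) b <- c(b, paste0(if (isTRUE(e$min_strict) ||
                                              is.null(e$min_strict)) "> "
                                          else ">= ", e$min))
    if (!is.null(e$max)) b <- c(b, paste0(if (isTRUE(e$max_strict) ||
                                              is.null(e$max_strict)) "< "
                                          else "<= ", e$max))
    paste0(e$space, ":", e$channel, " ", paste(b, collapse = ", "))
  }
  cat("  background:", paste(vapply(x$background, fmt_iv, character(1L)),
                             collapse = "; "), "\n")
  for (nm in names(x$features))
    cat("  feature ", nm, ": ",
        paste(vapply(x$features[[nm]], fmt_iv, character(1L)),
              collapse = "; "), "\n", sep = "")
  cat(sprintf("  despeckle %g (feature %g), min area %g, traits: %s\n",
              x$despeckle_radius, x$feature_despeckle_radius,
              x$min_object_area, paste(x$traits, collapse = ", ")))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration: %g mm over %g px\n",
                x$calibration$reference_length_mm,
                x$calibration$reference_px))
  invisible(x)
}
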