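#' Calibrated per-fruit and per-image trait measurement
#'
#' Masks and labeled objects are converted into physical trait values via
#' a scale calibration derived from a size reference of known length
#' (coin diameter, ruler edge) present in the staged photographs.
#'
#' @name measure
NULL

#' Build a scale calibration from a size reference
#'
#' `mm_per_px = reference_length_mm / (reference_px * downsize_scale)`.
#' `reference_px` is the pixel extent of the reference as measured on the
#' *original* image; `downsize_scale` is the working/original resolution
#' ratio recorded by [downsize()] (1 if the reference was measured on the
#' working image, or no downsizing occurred). The calibration is taken
#' from a single sample image and applied batch-wide, which assumes a
#' fixed camera height across the batch.
#'
#' @param reference_length_mm physical length of the reference (mm).
#' @param reference_px pixel extent of the reference.
#' @param downsize_scale working/original scale ratio (default 1).
#' @return an object of class `calibration` with field `mm_per_px`.
#' @examples
#' calibrate_scale(50, 200)  # 0.25 mm per pixel
#' @export
calibrate_scale <- function(reference_length_mm, reference_px,
                            downsize_scale = 1) {
  v <- c(reference_length_mm, reference_px, downsize_scale)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("calibration inputs must all be positive", call. = FALSE)
  structure(list(reference_length_mm = reference_length_mm,
                 reference_px = reference_px,
                 downsize_scale = downsize_scale,
                 mm_per_px = reference_length_mm /
                   (reference_px * downsize_scale)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g mm/px (%g mm over %g px, scale %g)\n",
              x$mm_per_px, x$reference_length_mm, x$reference_px,
              x$downsize_scale))
  invisible(x)
}

#' Measure all labeled objects
#'
#' Fruit length is the *vertical image-axis* pixel extent of the object
#' (uppermost to lowest detected pixel, inclusive, so a single-pixel
#' object has extent 1), and width the horizontal extent. This makes
#' measurements orientation-dependent by design: fruit must be staged
#' upright. Set `length_mode = "major_axis"` to instead report the extent
#' along the object's principal axis (and width across it).
#' Area is `n_pixels * mm_per_px^2`.
#'
#' Flags: `touches_border` marks objects clipped by the image edge;
#' `merged_suspect` marks objects larger than 2.5 times the median object
#' area, which in practice are several touching fruit labeled as one.
#'
#' @param objects a [label_objects()] result.
#' @param cal a [calibrate_scale()] calibration, or `NULL` for pixel-only
#'   output (mm columns `NA`).
#' @param length_mode `"bbox"` (default) or `"major_axis"`.
#' @return data frame with one row per object: `label`, `n_pixels`,
#'   `length_px`, `width_px`, `length_mm`, `width_mm`, `area_mm2`,
#'   `touches_border`, `merged_suspect`.
#' @export
measure_objects <- function(objects, cal = NULL, length_mode = "bbox") {
  stopifnot(inherits(objects, "labeled_objects"))
  length_mode <- match.arg(length_mode, c("bbox", "major_axis"))
  ob <- objects$objects
  d <- dim(objects$labels)
  if (nrow(ob) == 0L) {
    return(data.frame(label = integer(), n_pixels = integer(),
                      length_px = numeric(), width_px = numeric(),
                      length_mm = numeric(), width_mm = numeric(),
                      area_mm2 = numeric(), touches_border = logical(),
                      merged_suspect = logical()))
  }
  if (length_mode == "bbox") {
    length_px <- ob$max_row - ob$min_row + 1
    width_px <- ob$max_col - ob$min_col + 1
  } else {
    ext <- t(vapply(ob$label, function(k)
      principal_extent(objects$labels, k), numeric(2L)))
    length_px <- ext[, 1L]; width_px <- ext[, 2L]
  }
  mmpp <- if (is.null(cal)) NA_real_ else cal$mm_per_px
  med_area <- stats::median(ob$n_pixels)
  data.frame(
    label = ob$label,
    n_pixels = ob$n_pixels,
    length_px = length_px,
    width_px = width_px,
    length_mm = length_px * mmpp,
    width_mm = width_px * mmpp,
    area_mm2 = ob$n_pixels * mmpp^2,
    touches_border = ob$min_row == 1L | ob$max_row == d[1L] |
      ob$min_col == 1L | ob$max_col == d[2L],
    merged_suspect = ob$n_pixels > 2.5 * med_area,
    row.names = NULL)
}

#' Measure a single labeled object
#'
#' @inheritParams measure_objects
#' @param k object label.
#' @return single-row data frame (see [measure_objects()]).
#' @export
measure_object <- function(objects, k, cal = NULL, length_mode = "bbox") {
  res <- measure_objects(objects, cal, length_mode)
  row <- res[res$label == k, , drop = FALSE]
  if (nrow(row) == 0L) stop("no object with label ", k, call. = FALSE)
  row
}

# extent along/across the principal axis of an object's pixel cloud
principal_extent <- function(labels, k) {
  idx <- which(labels == k)
  r <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  if (length(idx) == 1L) return(c(1, 1))
  xy <- cbind(r, cc)
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  proj <- scale(xy, scale = FALSE) %*% ev
  c(diff(range(proj[, 1L])) + 1, diff(range(proj[, 2L])) + 1)
}

#' Feature pixel fraction, per image and per object
#'
#' The per-image value is `100 * |feature| / |fruit|` percent (the number
#' of feature pixels divided by the total number of non-background fruit
#' pixels); per-object values are computed analogously within each label.
#' An empty fruit mask yields 0 with a warning. The fraction is a pure
#' pixel ratio and is independent of any scale calibration.
#'
#' @param fruit logical fruit mask.
#' @param feature logical feature mask; must be a subset of `fruit`.
#' @param objects optional [label_objects()] result for per-object values.
#' @return list with `image_pct` (scalar) and `object_pct` (numeric
#'   vector along object labels, or `NULL` when `objects` not given).
#' @export
feature_fraction <- function(fruit, feature, objects = NULL) {
  stopifnot(identical(dim(fruit), dim(feature)))
  if (any(feature & !fruit))
    stop("`feature` must be a subset of `fruit`", call. = FALSE)
  n_fruit <- sum(fruit)
  if (n_fruit == 0L) {
    warning("empty fruit mask: feature fraction reported as 0", call. = FALSE)
    image_pct <- 0
  } else {
    image_pct <- 100 * sum(feature) / n_fruit
  }
  object_pct <- NULL
  if (!is.null(objects)) {
    stopifnot(inherits(objects, "labeled_objects"))
    n <- objects$n_objects
    if (n > 0L) {
      feat_counts <- tabulate(objects$labels[feature], nbins = n)
      lab_counts <- tabulate(objects$labels[objects$labels > 0L], nbins = n)
      object_pct <- 100 * feat_counts / lab_counts
    } else {
      object_pct <- numeric(0L)
    }
  }
  list(image_pct = image_pct, object_pct = object_pct)
}

#' Load a named-color chart
#'
#' Reads a CSV of named chart colors with columns `name, L, a, b`
#' (CIELAB). The bundled default, `rhs_chart_synthetic.csv`, is a
#' *synthetic approximation* of the Royal Horticultural Society colour
#' chart built from representative sRGB anchors (the RHS chart itself is
#' proprietary); it carries the published Greyed-Purple 185-A value
#' (L*a*b = 34.4, 42.0, 12.7) verbatim. Supply your own table for
#' faithful chart matching.
#'
#' @param path CSV path, or `NULL` for the bundled table.
#' @return data frame with columns `name`, `L`, `a`, `b`.
#' @export
color_chart <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rhs_chart_synthetic.csv",
                        package = "fruitpix", mustWork = TRUE)
  chart <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "L", "a", "b")
  if (!all(need %in% names(chart)))
    stop("color chart must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  chart[need]
}

#' Nearest chart entries for minimum, median and maximum feature colors
#'
#' Summarizes the pixels of a detected feature region by three colors:
#' the pixel of lowest and highest luminance (CIE Y of linear RGB; ties
#' broken lexicographically on R, G, B), and the channel-wise median
#' color. Each summary is matched to the nearest entry of a named-color
#' chart by Euclidean distance in CIELAB.
#'
#' @param img the [image_rgb()] the feature was detected on.
#' @param feature logical feature mask.
#' @param chart a [color_chart()] data frame (default: bundled table).
#' @return an object of class `color_profile`: list with `available`,
#'   `min_rgb`, `median_rgb`, `max_rgb`, and `matches` (data frame with
#'   `summary`, `name`, `distance`). When the feature mask is empty,
#'   `available = FALSE` and the other fields are `NULL`.
#' @export
color_profile <- function(img, feature, chart = color_chart()) {
  stopifnot(identical(dim(feature), dim(img)[1:2]))
  if (!any(feature)) {
    return(structure(list(available = FALSE, min_rgb = NULL,
                          median_rgb = NULL, max_rgb = NULL, matches = NULL),
                     class = "color_profile"))
  }
  px <- unclass(img)
  vals <- cbind(px[, , 1L][feature], px[, , 2L][feature], px[, , 3L][feature])
  lum <- as.numeric(srgb_to_linear(vals / 255) %*% .M_RGB2XYZ[2L, ])
  ord <- order(lum, vals[, 1L], vals[, 2L], vals[, 3L])
  min_rgb <- vals[ord[1L], ]
  max_rgb <- vals[ord[length(ord)], ]
  median_rgb <- apply(vals, 2L, stats::median)
  summaries <- rbind(min = min_rgb, median = median_rgb, max = max_rgb)
  lab <- rgb_to_lab(summaries)
  nn <- nearest_chart_color(lab, chart)
  structure(list(available = TRUE,
                 min_rgb = unname(min_rgb),
                 median_rgb = unname(median_rgb),
                 max_rgb = unname(max_rgb),
                 matches = data.frame(summary = c("min", "median", "max"),
                                      name = nn$name,
                                      distance = nn$distance,
                                      row.names = NULL)),
            class = "color_profile")
}

# vectorized nearest neighbour in Lab over the chart
nearest_chart_color <- function(lab, chart) {
  lab <- if (is.matrix(lab)) lab else matrix(lab, nrow = 1L)
  ref <- as.matrix(chart[c("L", "a", "b")])
  d2 <- outer(rowSums(lab^2), rowSums(ref^2), "+") - 2 * lab %*% t(ref)
  j <- apply(d2, 1L, which.min)
  # recompute the winning distance by direct subtraction: the expanded
  # form above cancels catastrophically when the distance is near zero
  dist <- sqrt(rowSums((lab - ref[j, , drop = FALSE])^2))
  list(name = chart$name[j], distance = dist)
}

#' @export
print.color_profile <- function(x, ...) {
  if (!x$available) {
    cat("<color_profile> (empty feature region)\n")
    return(invisible(x))
  }
  cat("<color_profile>\n")
  rgbs <- rbind(x$min_rgb, x$median_rgb, x$max_rgb)
  for (i in 1:3)
    cat(sprintf("  %-6s rgb(%s) -> %s (dE %.2f)\n",
                x$matches$summary[i],
                paste(round(rgbs[i, ], 1), collapse = ", "),
                x$matches$name[i], x$matches$distance[i]))
  invisible(x)
}
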