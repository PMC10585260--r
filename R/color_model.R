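#' Colorspace conversions and threshold evaluation
#'
#' Every stage of the pipeline classifies pixels by conjunctive per-channel
#' intervals across three colorspaces: sRGB (`R`,`G`,`B` on 0--255), HSB
#' (`H` in degrees `[0,360)`, `S`,`V` in `[0,1]`) and CIELAB (`L` in
#' `[0,100]`, `a`/`b` opponent axes). CIELAB is computed from sRGB under
#' the D65/2-degree white point via sRGB companding -> linear RGB -> XYZ ->
#' Lab, all in floating point.
#'
#' @name color_model
NULL

# sRGB -> XYZ (D65) matrix, IEC 61966-2-1
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
# D65 reference white = matrix row sums (so the white point maps to L=100,
# a=b=0 exactly under this matrix)
.WHITE_D65 <- as.numeric(.M_RGB2XYZ %*% c(1, 1, 1))

# coerce vector / n x 3 matrix / H x W x 3 array to n x 3 matrix,
# remembering how to restore the shape
as_channel_matrix <- function(x) {
  if (inherits(x, "image_rgb")) x <- unclass(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    list(m = matrix(x, ncol = 3L), shape = d)
  } else if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    list(m = x, shape = NULL)
  } else {
    stopifnot(length(x) == 3L)
    list(m = matrix(as.numeric(x), nrow = 1L), shape = "vector")
  }
}

restore_shape <- function(m, shape, names3) {
  if (is.null(shape)) {
    colnames(m) <- names3
    m
  } else if (identical(shape, "vector")) {
    stats::setNames(as.numeric(m[1L, ]), names3)
  } else {
    array(m, dim = shape)
  }
}

srgb_to_linear <- function(s) {
  ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
}

linear_to_srgb <- function(l) {
  ifelse(l <= 0.0031308, 12.92 * l, 1.055 * l^(1 / 2.4) - 0.055)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' Convert sRGB to CIELAB (D65/2 degrees)
#'
#' Accepts a single `c(r, g, b)` triple, an `n x 3` matrix, or an
#' `H x W x 3` raster, all on the 0--255 scale, and returns L/a/b in the
#' same shape. L is in `[0,100]`; a and b are unbounded opponent axes
#' (practically within about `[-128, 127]` for 8-bit input).
#'
#' @param x sRGB values on 0--255 (vector, matrix, or raster).
#' @return Lab values in the shape of the input.
#' @examples
#' rgb_to_lab(c(255, 255, 255))  # white point: L = 100, a = b = 0
#' @export
rgb_to_lab <- function(x) {
  cm <- as_channel_matrix(x)
  s <- cm$m / 255
  lin <- srgb_to_linear(s)
  xyz <- lin %*% t(.M_RGB2XYZ)
  fxyz <- lab_f(sweep(xyz, 2L, .WHITE_D65, "/"))
  lab <- cbind(116 * fxyz[, 2L] - 16,
               500 * (fxyz[, 1L] - fxyz[, 2L]),
               200 * (fxyz[, 2L] - fxyz[, 3L]))
  restore_shape(lab, cm$shape, c("L", "a", "b"))
}

#' Convert CIELAB (D65/2 degrees) back to sRGB
#'
#' Inverse of [rgb_to_lab()]. Out-of-gamut colors are clamped to `[0,255]`.
#'
#' @param x Lab values (vector, `n x 3` matrix, or `H x W x 3` array).
#' @param quantize round the result to 8-bit integers (default `FALSE`:
#'   keep floating point so a Lab triple round-trips exactly).
#' @return sRGB values on 0--255 in the shape of the input.
#' @export
lab_to_rgb <- function(x, quantize = FALSE) {
  cm <- as_channel_matrix(x)
  L <- cm$m[, 1L]; a <- cm$m[, 2L]; b <- cm$m[, 3L]
  fy <- (L + 16) / 116
  fx <- fy + a / 500
  fz <- fy - b / 200
  xyz <- cbind(lab_f_inv(fx), lab_f_inv(fy), lab_f_inv(fz))
  xyz <- sweep(xyz, 2L, .WHITE_D65, "*")
  lin <- xyz %*% t(.M_XYZ2RGB)
  s <- linear_to_srgb(pmax(lin, 0))
  out <- pmin(pmax(s * 255, 0), 255)
  if (quantize) out <- round(out)
  restore_shape(out, cm$shape, c("r", "g", "b"))
}

#' Convert sRGB to HSB (hue-saturation-brightness)
#'
#' Standard hexcone HSV transform. Hue is reported in degrees `[0, 360)`
#' (0 for achromatic pixels); saturation and brightness in `[0, 1]`.
#'
#' @param x sRGB values on 0--255 (vector, matrix, or raster).
#' @return HSB values in the shape of the input.
#' @export
rgb_to_hsb <- function(x) {
  cm <- as_channel_matrix(x)
  hsv <- t(grDevices::rgb2hsv(t(cm$m), maxColorValue = 255))
  hsv[, 1L] <- hsv[, 1L] * 360
  hsv[, 1L][hsv[, 1L] >= 360] <- 0
  restore_shape(hsv, cm$shape, c("h", "s", "v"))
}

#' Map CIELAB to the ImageJ 0--255 convention
#'
#' ImageJ's color thresholder expresses L*, a*, b* on a 0--255 scale
#' (`L*255/100`, `a+128`, `b+128`, clamped). This mapping lets users port
#' threshold settings chosen in ImageJ; for example an a* cutoff of 10 on
#' the CIELAB scale corresponds to the familiar ImageJ cutoff of 138.
#'
#' @param x Lab values (vector, matrix, or raster).
#' @return values on the 0--255 scale in the shape of the input.
#' @export
lab_to_imagej_scale <- function(x) {
  cm <- as_channel_matrix(x)
  out <- cbind(cm$m[, 1L] * 255 / 100, cm$m[, 2L] + 128, cm$m[, 3L] + 128)
  out <- pmin(pmax(out, 0), 255)
  restore_shape(out, cm$shape, c("L255", "a255", "b255"))
}

# inverse of the ImageJ mapping, applied to threshold bounds at config load
imagej_scale_to_lab_bound <- function(channel, value) {
  switch(channel,
         L = value * 100 / 255,
         a = ,
         b = value - 128,
         value)
}

CHANNELS <- c("R", "G", "B", "H", "S", "V", "L", "a", "b")

#' A per-channel acceptance interval
#'
#' One bound (or both) may be left `NULL`, meaning open on that side; a
#' fully open interval is the "full range" (FR) convention and imposes no
#' constraint. Bounds are strict (`>` / `<`) by default, matching the
#' convention in which a cutoff like `a > 7.51` excludes the boundary;
#' inclusive bounds are available via `min_strict`/`max_strict`.
#'
#' For every channel except hue, `min < max` is required when both bounds
#' are set. For `H` (degrees), `min > max` denotes a wraparound interval,
#' e.g. 350--10 degrees crossing 0.
#'
#' @param channel one of `R,G,B,H,S,V,L,a,b` (`b` is the CIELAB
#'   blue-yellow axis; `B` is the RGB blue channel).
#' @param min,max lower/upper bound, or `NULL` for open.
#' @param min_strict,max_strict logical; strict (`>`) or inclusive (`>=`).
#' @return an object of class `channel_interval`.
#' @export
channel_interval <- function(channel, min = NULL, max = NULL,
                             min_strict = TRUE, max_strict = TRUE) {
  if (!is.character(channel) || length(channel) != 1L ||
      !channel %in% CHANNELS)
    stop("`channel` must be one of: ", paste(CHANNELS, collapse = ", "),
         call. = FALSE)
  for (v in list(min, max))
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v)))
      stop("interval bounds must be single finite numbers", call. = FALSE)
  if (!is.null(min) && !is.null(max) && min >= max && channel != "H")
    stop("interval for channel ", channel, " requires min < max", call. = FALSE)
  structure(list(channel = channel, min = min, max = max,
                 min_strict = isTRUE(min_strict),
                 max_strict = isTRUE(max_strict)),
            class = "channel_interval")
}

#' A conjunctive multi-channel threshold
#'
#' A pixel passes the threshold iff it satisfies *every* interval;
#' channels not mentioned impose no constraint (full range).
#'
#' @param ... [channel_interval()] objects (or a single list of them).
#' @return an object of class `threshold_spec`.
#' @examples
#' # background removal: keep pixels with a* > -10, L* and b* full range
#' threshold_spec(channel_interval("a", min = -10))
#' @export
threshold_spec <- function(...) {
  ivs <- list(...)
  if (length(ivs) == 1L && is.list(ivs[[1L]]) &&
      !inherits(ivs[[1L]], "channel_interval"))
    ivs <- ivs[[1L]]
  ok <- vapply(ivs, inherits, logical(1L), "channel_interval")
  if (!all(ok))
    stop("all arguments must be channel_interval objects", call. = FALSE)
  chans <- vapply(ivs, `[[`, character(1L), "channel")
  if (anyDuplicated(chans))
    stop("at most one interval per channel; duplicated: ",
         paste(unique(chans[duplicated(chans)]), collapse = ", "),
         call. = FALSE)
  structure(list(intervals = ivs), class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  if (length(x$intervals) == 0L) {
    cat("<threshold_spec> (empty: full range, accepts everything)\n")
    return(invisible(x))
  }
  cat("<threshold_spec>\n")
  for (iv in x$intervals) {
    lo <- if (is.null(iv$min)) "-open" else
      paste0(if (iv$min_strict) "> " else ">= ", iv$min)
    hi <- if (is.null(iv$max)) "open" else
      paste0(if (iv$max_strict) "< " else "<= ", iv$max)
    cat(sprintf("  %s: %s, %s\n", iv$channel, lo, hi))
  }
  invisible(x)
}

# which derived spaces does this spec need?
spec_spaces <- function(spec) {
  chans <- vapply(spec$intervals, `[[`, character(1L), "channel")
  c(hsb = any(chans %in% c("H", "S", "V")),
    lab = any(chans %in% c("L", "a", "b")))
}

channel_values <- function(img, channel, lab = NULL, hsb = NULL) {
  px <- unclass(img)
  switch(channel,
         R = as.vector(px[, , 1L]),
         G = as.vector(px[, , 2L]),
         B = as.vector(px[, , 3L]),
         H = hsb[, 1L], S = hsb[, 2L], V = hsb[, 3L],
         L = lab[, 1L], a = lab[, 2L], b = lab[, 3L])
}

interval_pass <- function(values, iv) {
  if (iv$channel == "H" && !is.null(iv$min) && !is.null(iv$max) &&
      iv$min > iv$max) {
    # wraparound hue interval, e.g. 350 -> 10 degrees
    lo <- if (iv$min_strict) values > iv$min else values >= iv$min
    hi <- if (iv$max_strict) values < iv$max else values <= iv$max
    return(lo | hi)
  }
  pass <- rep(TRUE, length(values))
  if (!is.null(iv$min))
    pass <- pass & (if (iv$min_strict) values > iv$min else values >= iv$min)
  if (!is.null(iv$max))
    pass <- pass & (if (iv$max_strict) values < iv$max else values <= iv$max)
  pass
}

#' Evaluate a conjunctive threshold over a raster
#'
#' Converts the image to each constrained colorspace once, evaluates every
#' interval, and returns the pixelwise conjunction as a logical mask of the
#' same height and width. An empty spec accepts every pixel (with a
#' warning), mirroring the full-range convention.
#'
#' @param img an [image_rgb()] raster.
#' @param spec a [threshold_spec()].
#' @return logical `H x W` matrix.
#' @export
apply_threshold <- function(img, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  d <- dim(img)
  if (length(spec$intervals) == 0L) {
    warning("empty threshold spec: accepting all pixels (full range)",
            call. = FALSE)
    return(matrix(TRUE, d[1L], d[2L]))
  }
  need <- spec_spaces(spec)
  m <- as_channel_matrix(img)$m
  lab <- if (need[["lab"]]) rgb_to_lab(m) else NULL
  hsb <- if (need[["hsb"]]) rgb_to_hsb(m) else NULL
  pass <- rep(TRUE, d[1L] * d[2L])
  for (iv in spec$intervals)
    pass <- pass & interval_pass(channel_values(img, iv$channel, lab, hsb), iv)
  matrix(pass, d[1L], d[2L])
}
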