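#' Image preprocessing before segmentation
#'
#' Raw photographs are normalized in a fixed order before any thresholding:
#' downsize (bound the maximum dimension), contrast normalization (stretch
#' to the full RGB range), enhancement (median denoise then unsharp mask),
#' and finally exclusion-zone flagging for cropped regions. Each step is
#' individually toggleable from the configuration.
#'
#' @name preprocess
NULL

clamp8 <- function(x) pmin(pmax(x, 0), 255)

to_ebimage <- function(img) {
  EBImage::Image(aperm(unclass(img), c(2L, 1L, 3L)) / 255,
                 colormode = "Color")
}

from_ebimage <- function(eb) {
  clamp8(aperm(EBImage::imageData(eb), c(2L, 1L, 3L)) * 255)
}

#' Downsize an image so its maximum dimension does not exceed a bound
#'
#' Images whose largest dimension already fits are returned unchanged.
#' Otherwise the image is rescaled (bilinear interpolation) so that the
#' maximum dimension equals `max_dim`, preserving aspect ratio to within
#' one pixel of rounding. The applied scale factor is recorded on the
#' result so that pixel calibrations taken on the original image can be
#' corrected downstream.
#'
#' @param img an [image_rgb()].
#' @param max_dim positive integer bound on the maximum dimension
#'   (default 1500).
#' @return an [image_rgb()] with `scale_factor` attribute updated.
#' @export
downsize <- function(img, max_dim = 1500) {
  if (!is.numeric(max_dim) || length(max_dim) != 1L || max_dim < 1)
    stop("`max_dim` must be a positive integer", call. = FALSE)
  d <- dim(img)
  if (max(d[1:2]) <= max_dim) return(img)
  s <- max_dim / max(d[1:2])
  if (d[1L] >= d[2L]) {
    h <- as.integer(max_dim); w <- as.integer(round(d[2L] * s))
  } else {
    w <- as.integer(max_dim); h <- as.integer(round(d[1L] * s))
  }
  w <- max(w, 1L); h <- max(h, 1L)
  eb <- EBImage::resize(to_ebimage(img), w = w, h = h)  # bilinear
  replace_pixels(img, round(from_ebimage(eb)),
                 scale_factor = (attr(img, "scale_factor") %||% 1) * s)
}

#' Stretch pixel values to span the full RGB range
#'
#' Linear contrast stretch `x -> (x - m) * 255 / (M - m)` where `m` and
#' `M` are the joint minimum and maximum over all three channels. The
#' joint (rather than per-channel) stretch preserves hue: per-channel
#' stretching would shift colors and silently move them across CIELAB
#' thresholds. Constant images are returned unchanged.
#'
#' @param img an [image_rgb()].
#' @return an [image_rgb()] spanning `[0, 255]` (unless constant).
#' @export
normalize_contrast <- function(img) {
  px <- unclass(img)
  m <- min(px); M <- max(px)
  if (M <= m) return(img)
  replace_pixels(img, clamp8(round((px - m) * 255 / (M - m))))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Denoise and sharpen
#'
#' A median filter of window `(2 * denoise_radius + 1)^2` per channel
#' suppresses isolated noisy pixel values, followed by an unsharp mask
#' `x + amount * (x - blur(x))` (Gaussian blur, sigma 1) that sharpens
#' differences in color intensity. `denoise_radius = 0` and
#' `sharpen_amount = 0` yield the identity, which reproduces a pipeline
#' without pre-processing.
#'
#' @param img an [image_rgb()].
#' @param sharpen_amount unsharp-mask strength (>= 0, default 1).
#' @param denoise_radius median filter radius (>= 0, default 1).
#' @return an [image_rgb()].
#' @export
enhance <- function(img, sharpen_amount = 1, denoise_radius = 1) {
  if (!is.numeric(sharpen_amount) || sharpen_amount < 0)
    stop("`sharpen_amount` must be >= 0", call. = FALSE)
  if (!is.numeric(denoise_radius) || denoise_radius < 0)
    stop("`denoise_radius` must be >= 0", call. = FALSE)
  denoise_radius <- as.integer(denoise_radius)
  if (denoise_radius == 0L && sharpen_amount == 0) return(img)
  px <- unclass(img)
  if (denoise_radius > 0L) {
    eb <- EBImage::medianFilter(to_ebimage(replace_pixels(img, px)),
                                size = denoise_radius)
    px <- from_ebimage(eb)
  }
  if (sharpen_amount > 0) {
    k <- gaussian_kernel(1)
    blurred <- vapply(1:3, function(ch)
      filter2_reflect(px[, , ch], k), px[, , 1L])
    px <- clamp8(px + sharpen_amount * (px - blurred))
  }
  replace_pixels(img, round(px))
}

# 2-D convolution with edge replication (avoids EBImage's circular wrap,
# which would bleed opposite borders into each other)
filter2_reflect <- function(mat, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  h <- nrow(mat); w <- ncol(mat)
  pad <- mat[c(rep(1L, r), 1:h, rep(h, r)), c(rep(1L, r), 1:w, rep(w, r))]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kernel)))
    for (j in seq_len(ncol(kernel)))
      out <- out + kernel[i, j] * pad[i:(i + h - 1L), j:(j + w - 1L)]
  out
}

#' A fractional crop region applied batch-wide
#'
#' Coordinates are fractions of the image dimensions, half-open
#' `[top, bottom) x [left, right)`, so one region (for example the area
#' surrounding the size reference) applies uniformly to every image in a
#' batch regardless of resolution.
#'
#' @param top,left,bottom,right fractions in `[0, 1]` with `top < bottom`
#'   and `left < right`.
#' @return an object of class `crop_region`.
#' @export
crop_region <- function(top, left, bottom, right) {
  v <- c(top = top, left = left, bottom = bottom, right = right)
  if (!all(is.finite(v)) || any(v < 0) || any(v > 1))
    stop("crop fractions must lie in [0, 1]", call. = FALSE)
  if (top >= bottom || left >= right)
    stop("crop region requires top < bottom and left < right", call. = FALSE)
  structure(as.list(v), class = "crop_region")
}

#' Exclusion mask for a crop region
#'
#' Pixels inside the excluded region are flagged ineligible for all
#' downstream masks. The exclusion is represented as a mask rather than by
#' geometric removal so pixel coordinates stay comparable across stages.
#'
#' @param dims integer `c(H, W)` of the working image.
#' @param region a [crop_region()], or `NULL` for no exclusion.
#' @return logical `H x W` matrix, `TRUE` where pixels are excluded.
#' @export
exclusion_mask <- function(dims, region = NULL) {
  h <- dims[1L]; w <- dims[2L]
  mask <- matrix(FALSE, h, w)
  if (is.null(region)) return(mask)
  stopifnot(inherits(region, "crop_region"))
  rows <- which(seq_len(h) - 1L >= region$top * h &
                seq_len(h) - 1L < region$bottom * h)
  cols <- which(seq_len(w) - 1L >= region$left * w &
                seq_len(w) - 1L < region$right * w)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("crop region is degenerate (zero area) at this image size",
         call. = FALSE)
  mask[rows, cols] <- TRUE
  mask
}

#' Run the full preprocessing chain
#'
#' Fixed order: downsize, then contrast normalization, then enhancement.
#' Exclusion-zone flagging is handled separately (see [exclusion_mask()])
#' because it produces a mask, not pixels.
#'
#' @param img an [image_rgb()].
#' @param max_dim maximum dimension bound (see [downsize()]).
#' @param normalize apply [normalize_contrast()]?
#' @param sharpen_amount,denoise_radius see [enhance()].
#' @return preprocessed [image_rgb()].
#' @export
preprocess_image <- function(img, max_dim = 1500, normalize = TRUE,
                             sharpen_amount = 1, denoise_radius = 1) {
  img <- downsize(img, max_dim)
  if (isTRUE(normalize)) img <- normalize_contrast(img)
  enhance(img, sharpen_amount = sharpen_amount,
          denoise_radius = denoise_radius)
}
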