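#' RGB raster container
#'
#' `fruitpix` represents a photograph as a plain numeric array of dimension
#' H x W x 3 holding sRGB channel values on the 0--255 scale, row-major
#' with the origin at the top-left corner. Values are integer-valued after
#' decoding or preprocessing, but fractional values are accepted everywhere
#' (internal computation is floating point; nothing is quantized to 8 bits
#' except at encode time).
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 255]`.
#' @param source_path optional path the raster was decoded from.
#' @param original_dims integer `c(H0, W0)` of the image before any
#'   downsizing; defaults to the current dimensions.
#' @param scale_factor ratio of working resolution to original resolution
#'   (1 when no downsizing has been applied). Needed to correct pixel
#'   calibrations measured on the original image.
#' @return an object of class `image_rgb`.
#' @seealso [read_image_rgb()], [downsize()]
#' @export
image_rgb <- function(pixels, source_path = NA_character_,
                      original_dims = NULL, scale_factor = 1) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must be finite and within [0, 255]", call. = FALSE)
  if (is.null(original_dims)) original_dims <- dim(pixels)[1:2]
  structure(pixels,
            source_path = source_path,
            original_dims = as.integer(original_dims),
            scale_factor = as.numeric(scale_factor),
            class = c("image_rgb", "array"))
}

#' @export
print.image_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_rgb> %d x %d px", d[1], d[2]))
  sf <- attr(x, "scale_factor")
  if (!is.null(sf) && sf != 1) cat(sprintf(" (downsized, scale %.4f)", sf))
  sp <- attr(x, "source_path")
  if (!is.na(sp)) cat("  [", sp, "]", sep = "")
  cat("\n")
  invisible(x)
}

# rebuild an image_rgb around new pixel data, carrying provenance forward
replace_pixels <- function(img, pixels, scale_factor = NULL) {
  image_rgb(pixels,
            source_path = attr(img, "source_path") %||% NA_character_,
            original_dims = attr(img, "original_dims") %||% dim(pixels)[1:2],
            scale_factor = scale_factor %||%
              (attr(img, "scale_factor") %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a photograph into an `image_rgb` raster
#'
#' Decodes JPEG, PNG or TIFF via EBImage. Grayscale images are expanded to
#' three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path path to the image file.
#' @return an [image_rgb()] with `source_path` set.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] > 3L) {
    px <- px[, , 1:3, drop = FALSE]
  } else if (dim(px)[3] < 3L) {
    stop("unsupported channel count in ", path, call. = FALSE)
  }
  # EBImage stores x (width) first; transpose to row-major H x W
  px <- aperm(px, c(2L, 1L, 3L))
  px <- round(pmin(pmax(px, 0), 1) * 255)
  image_rgb(px, source_path = path)
}

#' Write an `image_rgb` raster to disk
#'
#' @param img an [image_rgb()] (or plain H x W x 3 array on 0--255).
#' @param path output path; format chosen by extension (png/jpg/tiff).
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  px <- pmin(pmax(unclass(img), 0), 255) / 255
  EBImage::writeImage(
    EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask (or fruit/feature overlay) as an image
#'
#' With only `fruit` given, writes a black-and-white mask. With `feature`
#' also given, writes fruit pixels in white and feature pixels in red, for
#' visual post-analysis quality checking.
#'
#' @param fruit logical H x W matrix.
#' @param path output path.
#' @param feature optional logical H x W matrix, subset of `fruit`.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(fruit, path, feature = NULL) {
  h <- nrow(fruit); w <- ncol(fruit)
  px <- array(0, dim = c(h, w, 3L))
  px[, , 1][fruit] <- 255; px[, , 2][fruit] <- 255; px[, , 3][fruit] <- 255
  if (!is.null(feature)) {
    px[, , 2][feature] <- 40
    px[, , 3][feature] <- 40
    px[, , 1][feature] <- 220
  }
  write_image_rgb(image_rgb(px), path)
}
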