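#' Segmentation: masks and labeled fruit objects
#'
#' A preprocessed image is turned into (1) a fruit mask by thresholding
#' plus despeckling, (2) a feature mask (e.g. reverted drupelet pixels)
#' constrained to lie inside the fruit mask, and (3) labeled fruit objects
#' as 8-connected components filtered by a minimum area.
#'
#' @name segment
NULL

# disc structuring element: offsets with dx^2 + dy^2 <= r^2
disc_brush <- function(radius) {
  d <- outer((-radius:radius)^2, (-radius:radius)^2, "+")
  (d <= radius^2) * 1
}

#' Remove small isolated pixel groups by morphological opening
#'
#' Successive shrinking (erosion) and swelling (dilation) of detected
#' pixel groups with a disc structuring element of the given radius.
#' Groups too small to survive the erosion (dust, juice, debris) are
#' removed entirely; larger groups keep their overall shape, with convex
#' corners slightly rounded. `radius = 0` is the identity. Pixels outside
#' the image are treated as background.
#'
#' @param mask logical `H x W` matrix.
#' @param radius disc radius in pixels (>= 0).
#' @return logical `H x W` matrix, always a subset of `mask`.
#' @export
despeckle <- function(mask, radius) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("`radius` must be a single number >= 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius == 0L || !any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  # pad with background so border semantics are unambiguous
  pad <- matrix(FALSE, h + 2L * radius, w + 2L * radius)
  pad[radius + (1:h), radius + (1:w)] <- mask
  eb <- EBImage::Image(t(pad) * 1)
  opened <- EBImage::dilate(EBImage::erode(eb, disc_brush(radius)),
                            disc_brush(radius))
  out <- t(EBImage::imageData(opened)) > 0.5
  out[radius + (1:h), radius + (1:w), drop = FALSE]
}

#' Segment fruit pixels from the background
#'
#' Applies the background-removal threshold, clears any excluded crop
#' zone, then despeckles. The result is the set of fruit pixels, i.e. the
#' denominator of all feature fractions. An empty result is legal (the
#' per-image record downstream gets zero objects) and only warns.
#'
#' @param img preprocessed [image_rgb()].
#' @param spec background-removal [threshold_spec()] (pixels *passing* the
#'   threshold are fruit).
#' @param despeckle_radius opening radius (see [despeckle()]).
#' @param exclusion optional logical exclusion mask (`TRUE` = ineligible).
#' @return logical fruit mask.
#' @export
remove_background <- function(img, spec, despeckle_radius = 2,
                              exclusion = NULL) {
  mask <- apply_threshold(img, spec)
  if (!is.null(exclusion)) {
    stopifnot(identical(dim(exclusion), dim(mask)))
    mask <- mask & !exclusion
  }
  mask <- despeckle(mask, despeckle_radius)
  if (!any(mask))
    warning("empty segmentation: no fruit pixels detected", call. = FALSE)
  mask
}

#' Detect a color-defined feature within the fruit mask
#'
#' Applies the feature threshold, intersects with the fruit mask,
#' despeckles, and re-intersects so that the guarantee `feature` is a
#' subset of `fruit` holds even at despeckle boundaries.
#'
#' @param img preprocessed [image_rgb()] (same image the fruit mask came
#'   from).
#' @param fruit logical fruit mask from [remove_background()].
#' @param spec feature [threshold_spec()] (e.g. `a > 16.15` for reverted
#'   drupelet pixels).
#' @param despeckle_radius opening radius.
#' @return logical feature mask, subset of `fruit`.
#' @export
detect_feature <- function(img, fruit, spec, despeckle_radius = 1) {
  stopifnot(identical(dim(fruit), dim(img)[1:2]))
  mask <- apply_threshold(img, spec) & fruit
  despeckle(mask, despeckle_radius) & fruit
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label fruit objects as 8-connected components
#'
#' Connected-component labeling with 8-connectivity (diagonal pixels
#' connect). Components smaller than `min_object_area` pixels are
#' dropped. Surviving labels are renumbered 1..n in row-major order of
#' each component's first pixel, for deterministic output.
#'
#' @param mask logical fruit mask.
#' @param min_object_area minimum component pixel count (>= 1).
#' @return an object of class `labeled_objects`: list with `labels`
#'   (integer `H x W`, 0 = background), `n_objects`, and `objects`, a
#'   data frame of per-object pixel counts and bounding boxes
#'   (`label`, `n_pixels`, `min_row`, `max_row`, `min_col`, `max_col`).
#' @export
label_objects <- function(mask, min_object_area = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!is.numeric(min_object_area) || min_object_area < 1)
    stop("`min_object_area` must be >= 1", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  # first pass: 4-connected labels, then merge labels touching diagonally
  lab4 <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1))))
  storage.mode(lab4) <- "integer"
  n4 <- max(lab4)
  if (n4 == 0L) {
    return(structure(list(labels = lab4, n_objects = 0L,
                          objects = data.frame(label = integer(),
                                               n_pixels = integer(),
                                               min_row = integer(),
                                               max_row = integer(),
                                               min_col = integer(),
                                               max_col = integer())),
                     class = "labeled_objects"))
  }
  parent <- seq_len(n4)
  if (h > 1L && w > 1L) {
    # diagonal neighbor pairs with two different positive labels
    a1 <- lab4[-h, -w]; b1 <- lab4[-1L, -1L]   # down-right
    a2 <- lab4[-h, -1L]; b2 <- lab4[-1L, -w]   # down-left
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[k, 1L])
      rb <- uf_find(parent, pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n4), function(i) uf_find(parent, i), integer(1L))
  merged <- matrix(0L, h, w)
  fg <- lab4 > 0L
  merged[fg] <- root[lab4[fg]]

  sizes <- tabulate(merged[fg], nbins = n4)
  keep <- which(sizes >= min_object_area)
  if (length(keep) == 0L) {
    labels <- matrix(0L, h, w)
    return(structure(list(labels = labels, n_objects = 0L,
                          objects = data.frame(label = integer(),
                                               n_pixels = integer(),
                                               min_row = integer(),
                                               max_row = integer(),
                                               min_col = integer(),
                                               max_col = integer())),
                     class = "labeled_objects"))
  }
  # order kept components by row-major position of their first pixel
  idx <- which(fg)
  rows <- (idx - 1L) %% h + 1L
  cols <- (idx - 1L) %/% h + 1L
  rowmajor <- (rows - 1L) * w + cols
  first_px <- rep(NA_integer_, n4)
  comp <- merged[fg]
  in_keep <- comp %in% keep
  first_px[keep] <- vapply(keep, function(kk)
    min(rowmajor[in_keep & comp == kk]), integer(1L))
  keep <- keep[order(first_px[keep])]
  relabel <- rep(0L, n4)
  relabel[keep] <- seq_along(keep)
  labels <- matrix(0L, h, w)
  labels[fg] <- relabel[comp]

  obj_rows <- rows[labels[idx] > 0L]
  obj_cols <- cols[labels[idx] > 0L]
  obj_lab <- labels[idx][labels[idx] > 0L]
  objects <- data.frame(
    label = seq_along(keep),
    n_pixels = as.integer(tabulate(obj_lab, nbins = length(keep))),
    min_row = as.integer(tapply(obj_rows, obj_lab, min)),
    max_row = as.integer(tapply(obj_rows, obj_lab, max)),
    min_col = as.integer(tapply(obj_cols, obj_lab, min)),
    max_col = as.integer(tapply(obj_cols, obj_lab, max)),
    row.names = NULL)
  structure(list(labels = labels, n_objects = length(keep),
                 objects = objects),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s), %d x %d px\n",
              x$n_objects, nrow(x$labels), ncol(x$labels)))
  if (x$n_objects > 0L) print(x$objects)
  invisible(x)
}
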