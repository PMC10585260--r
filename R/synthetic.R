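#' Synthetic staged-photograph scenes with exact ground truth
#'
#' Emulates the study's staged photographs — dark berries on a green
#' cutting board with a size-reference bar of known physical length,
#' debris specks, and a sub-population of reverted (red) drupelet discs —
#' so every pipeline stage can be validated against exact pixel-level
#' truth without real photographs. With `anti_alias = FALSE` every
#' rendered pixel is exactly one palette color and all truth counts are
#' exact; with `anti_alias = TRUE` the scene is rendered at 3x and
#' block-averaged, producing realistic blended boundary pixels.
#'
#' The default palette is chosen so the CIELAB a* values of its classes
#' straddle realistic thresholds for this kind of imagery: board a* is
#' far below every background cutoff, berry-body a* sits between the
#' background cutoffs and the reverted-detection cutoffs, and reverted
#' red sits far above them. This separation is asserted at render time.
#'
#' @name synthetic_fixtures
NULL

.DEFAULT_PALETTE <- list(
  background = c(60, 120, 60),   # green board,    a* ~ -33
  body       = c(25, 15, 20),    # black drupelet, a* ~ +5
  reverted   = c(150, 40, 40),   # reverted red,   a* ~ +45
  speck      = c(120, 50, 50),   # juice/debris,   a* ~ +31 (despeckle prey)
  bar        = c(0, 130, 130))   # reference bar,  a* ~ -29 (never fruit)

# evaluate code under a fixed RNG state without disturbing the caller's
run_seeded <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic scene
#'
#' @param width,height scene dimensions in pixels.
#' @param n_berries number of berries (ellipses of packed drupelets).
#' @param reverted_fraction target fraction of fruit *pixels* drawn in
#'   the reverted color, in `[0, 1]`, applied per berry. Reverted
#'   drupelet discs are added until the red pixel budget
#'   `f * berry_area` is met (`f = 1` fills the berry entirely).
#' @param berry_ry,berry_rx mean vertical/horizontal berry semi-axes in
#'   pixels (each berry jittered by up to 8 percent, from `seed`).
#' @param drupelet_radius radius of the reverted drupelet discs.
#' @param n_specks number of debris specks scattered on the background.
#' @param speck_radius speck disc radius (0 = single pixel).
#' @param bar_length_px,bar_length_mm pixel length and declared physical
#'   length of the size-reference bar (true scale =
#'   `bar_length_mm / bar_length_px`).
#' @param anti_alias render at 3x and block-average (blended boundaries)?
#' @param seed RNG seed fixing the scene exactly.
#' @param palette list of sRGB triples: `background`, `body`,
#'   `reverted`, `speck`, `bar`.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 440, height = 330, n_berries = 3,
                       reverted_fraction = 0.15,
                       berry_ry = 50, berry_rx = 36, drupelet_radius = 4,
                       n_specks = 5, speck_radius = 1,
                       bar_length_px = 120, bar_length_mm = 50,
                       anti_alias = FALSE, seed = 1,
                       palette = .DEFAULT_PALETTE) {
  stopifnot(width >= 64, height >= 64, n_berries >= 1,
            drupelet_radius >= 2, bar_length_px >= 4, bar_length_mm > 0,
            n_specks >= 0, speck_radius >= 0)
  if (!is.numeric(reverted_fraction) || reverted_fraction < 0 ||
      reverted_fraction > 1)
    stop("`reverted_fraction` must lie in [0, 1]", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_berries = as.integer(n_berries),
                 reverted_fraction = reverted_fraction,
                 berry_ry = berry_ry, berry_rx = berry_rx,
                 drupelet_radius = drupelet_radius,
                 n_specks = as.integer(n_specks),
                 speck_radius = as.integer(speck_radius),
                 bar_length_px = as.integer(bar_length_px),
                 bar_length_mm = bar_length_mm,
                 anti_alias = isTRUE(anti_alias), seed = as.integer(seed),
                 palette = palette),
            class = "scene_spec")
}

#' Assert that a palette's a* values straddle the working thresholds
#'
#' Background must fall below every realistic background-removal cutoff
#' (a* <= -12), berry body must sit strictly between the background
#' cutoffs and the reverted cutoffs (-8.5 < a* < 7.51), and reverted red
#' must exceed the most stringent reverted cutoff (a* > 16.15).
#'
#' @param palette palette list (see [scene_spec()]).
#' @return `TRUE` invisibly; stops if the separation fails.
#' @export
validate_palette <- function(palette = .DEFAULT_PALETTE) {
  a_of <- function(p) rgb_to_lab(p)[["a"]]
  if (!(a_of(palette$background) <= -12))
    stop("palette: background a* must be <= -12", call. = FALSE)
  if (!(a_of(palette$body) > -8.5 && a_of(palette$body) < 7.51))
    stop("palette: berry body a* must lie in (-8.5, 7.51)", call. = FALSE)
  if (!(a_of(palette$reverted) > 16.15))
    stop("palette: reverted a* must be > 16.15", call. = FALSE)
  if (!(a_of(palette$bar) <= -12))
    stop("palette: reference bar a* must be <= -12", call. = FALSE)
  invisible(TRUE)
}

# block-average a (k*h x k*w) matrix down to h x w
block_mean <- function(m, k) {
  if (k == 1L) return(m)
  h <- nrow(m) %/% k; w <- ncol(m) %/% k
  s <- rowsum(m, rep(seq_len(h), each = k))
  t(rowsum(t(s), rep(seq_len(w), each = k))) / k^2
}

#' Render a synthetic scene and its ground truth
#'
#' Deterministic given `spec$seed`. Ground truth (masks, counts,
#' extents, scale) is defined on the 1x pixel grid by exact geometry and
#' coincides pixel-for-pixel with the rendered image when
#' `anti_alias = FALSE`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (an [image_rgb()]) and `truth`: a list with
#'   `fruit_mask`, `feature_mask` (logical `H x W`), `fruit_px`,
#'   `reverted_px`, `fraction` (reverted/fruit pixel proportion),
#'   `mm_per_px`, and `berries`, a per-berry data frame (`label`,
#'   `n_pixels`, `reverted_px`, `min_row`, `max_row`, `min_col`,
#'   `max_col`) ordered row-major by first pixel (matching
#'   [label_objects()] ordering).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_palette(spec$palette)
  run_seeded(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  f <- spec$reverted_fraction
  rd <- spec$drupelet_radius

  # --- continuous geometry (units of 1x pixels; pixel centers at i-0.5) ---
  bar <- list(top = 9, bottom = 17, left = 20,
              right = 20 + spec$bar_length_px)
  if (bar$right > w - 10) stop("reference bar does not fit", call. = FALSE)

  nc <- ceiling(sqrt(spec$n_berries))
  nr <- ceiling(spec$n_berries / nc)
  band_top <- 34
  cell_w <- w / nc
  cell_h <- (h - band_top) / nr
  berries <- vector("list", spec$n_berries)
  for (i in seq_len(spec$n_berries)) {
    gi <- (i - 1L) %/% nc; gj <- (i - 1L) %% nc
    ry <- spec$berry_ry * stats::runif(1, 0.92, 1.08)
    rx <- spec$berry_rx * stats::runif(1, 0.92, 1.08)
    if (2 * rx > cell_w - 10 || 2 * ry > cell_h - 10)
      stop("berries cannot fit in the scene at these sizes", call. = FALSE)
    berries[[i]] <- list(cy = band_top + (gi + 0.5) * cell_h,
                         cx = (gj + 0.5) * cell_w, ry = ry, rx = rx)
  }

  # per-berry reverted drupelet discs on a hexagonal lattice
  for (i in seq_along(berries)) {
    b <- berries[[i]]
    centers <- hex_disc_centers(b, rd)
    b$mask1 <- ellipse_mask(h, w, b, k = 1L)
    b$n_pixels <- sum(b$mask1)
    if (f >= 1) {
      b$red <- NULL; b$fill_red <- TRUE
      b$reverted_px <- b$n_pixels
    } else {
      b$fill_red <- FALSE
      target <- f * b$n_pixels
      if (nrow(centers) > 0L) {
        counts <- disc_pixel_counts(centers, rd, h, w)
        ord <- sample.int(nrow(centers))
        cum <- cumsum(counts[ord])
        k_over <- which(cum >= target)[1L]
        k_sel <- if (is.na(k_over)) NA_integer_
                 else if (k_over > 1L &&
                          abs(cum[k_over - 1L] - target) <=
                          abs(cum[k_over] - target)) k_over - 1L
                 else k_over
        if (is.na(k_sel)) {
          if (target > 0 && max(cum) < 0.9 * target)
            stop("cannot reach requested reverted fraction: drupelet ",
                 "packing too sparse", call. = FALSE)
          k_sel <- length(cum)
        }
        if (target == 0) k_sel <- 0L
        sel <- ord[seq_len(k_sel)]
        b$red <- centers[sel, , drop = FALSE]
        b$reverted_px <- sum(counts[sel])
      } else {
        if (target > 0)
          stop("cannot reach requested reverted fraction: no drupelet ",
               "discs fit in berry", call. = FALSE)
        b$red <- centers; b$reverted_px <- 0L
      }
    }
    berries[[i]] <- b
  }

  # specks on the background, clear of berries and bar
  specks <- place_specks(spec, berries, bar)

  # --- truth on the 1x grid ---
  fruit_mask <- matrix(FALSE, h, w)
  feature_mask <- matrix(FALSE, h, w)
  for (b in berries) {
    fruit_mask <- fruit_mask | b$mask1
    if (isTRUE(b$fill_red)) {
      feature_mask <- feature_mask | b$mask1
    } else if (!is.null(b$red) && nrow(b$red) > 0L) {
      feature_mask <- feature_mask | discs_mask(h, w, b$red, rd, k = 1L)
    }
  }
  berry_df <- do.call(rbind, lapply(berries, function(b) {
    idx <- which(b$mask1)
    r <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
    data.frame(n_pixels = b$n_pixels, reverted_px = b$reverted_px,
               min_row = min(r), max_row = max(r),
               min_col = min(cc), max_col = max(cc))
  }))
  # row-major first-pixel ordering, matching label_objects()
  first_px <- vapply(berries, function(b) {
    idx <- which(b$mask1)
    r <- (idx - 1L) %% h + 1L; cc <- (idx - 1L) %/% h + 1L
    min((r - 1L) * w + cc)
  }, numeric(1L))
  berry_df <- berry_df[order(first_px), , drop = FALSE]
  berry_df <- cbind(label = seq_len(nrow(berry_df)), berry_df)
  rownames(berry_df) <- NULL

  # --- render (at 3x when anti-aliasing) ---
  k <- if (spec$anti_alias) 3L else 1L
  pal <- lapply(spec$palette, as.numeric)
  chan <- lapply(1:3, function(ch) matrix(pal$background[ch], k * h, k * w))
  paint <- function(mask, col)
    for (ch in 1:3) chan[[ch]][mask] <<- col[ch]
  paint(rect_mask(h, w, bar, k), pal$bar)
  for (b in berries) {
    paint(ellipse_mask(h, w, b, k), pal$body)
    if (isTRUE(b$fill_red)) {
      paint(ellipse_mask(h, w, b, k), pal$reverted)
    } else if (!is.null(b$red) && nrow(b$red) > 0L) {
      paint(discs_mask(h, w, b$red, rd, k), pal$reverted)
    }
  }
  if (nrow(specks) > 0L)
    paint(discs_mask(h, w, specks, spec$speck_radius, k, at_least_center = TRUE),
          pal$speck)
  px <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- round(block_mean(chan[[ch]], k))

  truth <- list(fruit_mask = fruit_mask, feature_mask = feature_mask,
                fruit_px = sum(fruit_mask),
                reverted_px = sum(feature_mask),
                fraction = if (sum(fruit_mask) > 0)
                  sum(feature_mask) / sum(fruit_mask) else 0,
                mm_per_px = spec$bar_length_mm / spec$bar_length_px,
                berries = berry_df,
                n_specks = nrow(specks))
  list(image = image_rgb(px), truth = truth)
}

# pixel-center coordinate grids at scale k (in 1x units)
grid_yx <- function(h, w, k) {
  list(y = (seq_len(k * h) - 0.5) / k, x = (seq_len(k * w) - 0.5) / k)
}

ellipse_mask <- function(h, w, b, k) {
  g <- grid_yx(h, w, k)
  dy2 <- ((g$y - b$cy) / b$ry)^2
  dx2 <- ((g$x - b$cx) / b$rx)^2
  outer(dy2, dx2, "+") <= 1
}

rect_mask <- function(h, w, r, k) {
  g <- grid_yx(h, w, k)
  outer(g$y >= r$top & g$y < r$bottom, g$x >= r$left & g$x < r$right, "&")
}

# hexagonal lattice of disc centers fully inside the berry ellipse
hex_disc_centers <- function(b, rd) {
  dy <- rd * sqrt(3)
  jmax <- ceiling(b$ry / dy)
  imax <- ceiling(b$rx / (2 * rd))
  cen <- NULL
  for (j in -jmax:jmax) {
    y <- b$cy + j * dy
    xs <- b$cx + (seq(-imax, imax) + (j %% 2) / 2) * 2 * rd
    cen <- rbind(cen, cbind(y = y, x = xs))
  }
  ry_in <- b$ry - rd; rx_in <- b$rx - rd
  if (ry_in <= 0 || rx_in <= 0) return(cen[0, , drop = FALSE])
  keep <- ((cen[, "y"] - b$cy) / ry_in)^2 +
          ((cen[, "x"] - b$cx) / rx_in)^2 <= 1
  cen[keep, , drop = FALSE]
}

# 1x pixel count of each disc (strict radius, so tangent discs stay disjoint)
disc_pixel_counts <- function(centers, rd, h, w) {
  vapply(seq_len(nrow(centers)), function(i) {
    yc <- centers[i, "y"]; xc <- centers[i, "x"]
    rs <- max(1L, floor(yc - rd)):min(h, ceiling(yc + rd))
    cs <- max(1L, floor(xc - rd)):min(w, ceiling(xc + rd))
    sum(outer((rs - 0.5 - yc)^2, (cs - 0.5 - xc)^2, "+") < rd^2)
  }, numeric(1L))
}

discs_mask <- function(h, w, centers, rd, k, at_least_center = FALSE) {
  m <- matrix(FALSE, k * h, k * w)
  for (i in seq_len(nrow(centers))) {
    yc <- centers[i, "y"]; xc <- centers[i, "x"]
    rs <- max(1L, floor((yc - rd) * k)):min(k * h, ceiling((yc + rd) * k))
    cs <- max(1L, floor((xc - rd) * k)):min(k * w, ceiling((xc + rd) * k))
    loc <- outer(((rs - 0.5) / k - yc)^2, ((cs - 0.5) / k - xc)^2, "+") < rd^2
    if (at_least_center && !any(loc)) {
      # guarantee specks of radius 0 still occupy their center pixel
      rs <- pmin(pmax(round(yc * k), 1L), k * h)
      cs <- pmin(pmax(round(xc * k), 1L), k * w)
      loc <- matrix(TRUE, 1L, 1L)
    }
    sub <- m[rs, cs, drop = FALSE]
    sub[loc] <- TRUE
    m[rs, cs] <- sub
  }
  m
}

place_specks <- function(spec, berries, bar) {
  n <- spec$n_specks
  out <- matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("y", "x")))
  if (n == 0L) return(out)
  h <- spec$height; w <- spec$width
  margin <- spec$speck_radius + 3
  tries <- 0L
  while (nrow(out) < n && tries < 200L * n) {
    tries <- tries + 1L
    y <- stats::runif(1, bar$bottom + margin + 2, h - margin)
    x <- stats::runif(1, margin, w - margin)
    clear <- all(vapply(berries, function(b)
      ((y - b$cy) / (b$ry + margin))^2 +
        ((x - b$cx) / (b$rx + margin))^2 > 1, logical(1L)))
    if (clear) out <- rbind(out, cbind(y = y, x = x))
  }
  out
}

#' Analysis configuration matched to the synthetic study conditions
#'
#' Builds the [pipeline_config()] used to validate the pipeline on
#' synthetic scenes. Pre-processing is disabled (the palette is designed
#' directly against the thresholds; contrast stretching would move colors
#' off their designed values, just as re-white-balancing a calibrated
#' chart would). The background cutoff is `a > -10`. The feature cutoff
#' is *calibrated from the palette*, mirroring how thresholds are chosen
#' on a representative sample image in real campaigns: it is set to the
#' a* value of the 50/50 sRGB blend of the berry-body and reverted
#' colors, which classifies anti-aliased boundary pixels at 50 percent
#' coverage and is therefore unbiased at object boundaries. The
#' reference-bar zone at the top of the scene is cropped out, as the
#' zone surrounding a size reference would be.
#'
#' @param spec a [scene_spec()] (supplies palette and bar geometry).
#' @param despeckle_radius,feature_despeckle_radius opening radii
#'   (defaults 2 and 1; the feature radius must stay below the drupelet
#'   disc radius). Set both to 0 for exact-count validation on
#'   `anti_alias = FALSE` scenes.
#' @return a [pipeline_config()].
#' @export
scene_analysis_config <- function(spec, despeckle_radius = 2,
                                  feature_despeckle_radius = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  pal <- spec$palette
  blend <- (as.numeric(pal$body) + as.numeric(pal$reverted)) / 2
  cutoff <- round(rgb_to_lab(blend)[["a"]], 2)
  pipeline_config(
    normalize = FALSE, sharpen_amount = 0, denoise_radius = 0,
    background = list(list(space = "lab", channel = "a", min = -10)),
    features = list(RDR = list(list(space = "lab", channel = "a",
                                    min = cutoff))),
    despeckle_radius = despeckle_radius,
    feature_despeckle_radius = feature_despeckle_radius,
    min_object_area = 50,
    calibration = list(reference_length_mm = spec$bar_length_mm,
                       reference_px = spec$bar_length_px),
    exclude_region = list(top = 0, left = 0,
                          bottom = round(30 / spec$height, 6), right = 1))
}

#' Compare pipeline results against scene ground truth
#'
#' Joins per-object pipeline output to per-berry truth (both are ordered
#' row-major by first pixel) and reports absolute recovery errors.
#' A mismatch in object count is reported, not raised.
#'
#' @param truth the `truth` element of a [render_scene()] result.
#' @param results per-object results: a data frame with columns
#'   `length_mm`, `width_mm` and a feature percentage column (the first
#'   column ending in `_pct` is used), ordered by object label — e.g. the
#'   object rows of [process_image()].
#' @return list with `n_truth`, `n_detected`, `count_mismatch`, and (for
#'   the paired objects) `length_err_mm`, `width_err_mm`, `fraction_err`
#'   (absolute error of the reverted pixel *proportion*), plus
#'   `mean_abs_fraction_err`, `max_abs_fraction_err`,
#'   `mean_abs_length_err_mm`, `max_abs_length_err_mm`.
#' @export
truth_report <- function(truth, results) {
  tb <- truth$berries
  n_t <- nrow(tb); n_d <- nrow(results)
  n <- min(n_t, n_d)
  pct_col <- grep("_pct$", names(results), value = TRUE)[1L]
  mmpp <- truth$mm_per_px
  true_len <- (tb$max_row - tb$min_row + 1) * mmpp
  true_wid <- (tb$max_col - tb$min_col + 1) * mmpp
  true_frac <- tb$reverted_px / tb$n_pixels
  idx <- seq_len(n)
  len_err <- abs(results$length_mm[idx] - true_len[idx])
  wid_err <- abs(results$width_mm[idx] - true_wid[idx])
  frac_err <- abs(results[[pct_col]][idx] / 100 - true_frac[idx])
  list(n_truth = n_t, n_detected = n_d, count_mismatch = n_t != n_d,
       length_err_mm = len_err, width_err_mm = wid_err,
       fraction_err = frac_err,
       mean_abs_fraction_err = mean(frac_err),
       max_abs_fraction_err = max(frac_err),
       mean_abs_length_err_mm = mean(len_err),
       max_abs_length_err_mm = max(len_err))
}

#' Write a set of synthetic scenes to disk
#'
#' Renders `n_scenes` scenes (seeds `seed, seed + 1, ...`) and writes
#' `scene_###.png` plus a `scene_###_truth.json` sidecar with the truth
#' counts and per-berry geometry (masks are omitted from the JSON).
#'
#' @param dir output directory (created if needed).
#' @param n_scenes number of scenes.
#' @param seed base seed.
#' @param ... passed to [scene_spec()].
#' @return data frame of scene paths and truth summaries, invisibly.
#' @export
write_scenes <- function(dir, n_scenes = 10, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_scenes), function(i) {
    sc <- render_scene(scene_spec(seed = seed + i - 1L, ...))
    png_path <- file.path(dir, sprintf("scene_%03d.png", i))
    write_image_rgb(sc$image, png_path)
    tr <- sc$truth
    jsonlite::write_json(
      list(fruit_px = tr$fruit_px, reverted_px = tr$reverted_px,
           fraction = tr$fraction, mm_per_px = tr$mm_per_px,
           n_specks = tr$n_specks, berries = tr$berries),
      file.path(dir, sprintf("scene_%03d_truth.json", i)),
      auto_unbox = TRUE, digits = NA)
    data.frame(path = png_path, fruit_px = tr$fruit_px,
               reverted_px = tr$reverted_px, fraction = tr$fraction)
  })
  invisible(do.call(rbind, rows))
}
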