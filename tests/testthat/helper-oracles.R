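# Independent brute-force oracles used across the suite. These share only
# the *definitions* (disc structuring element, 8-connectivity) with the
# implementation, never its algorithms or library calls.

# shift a logical matrix so out[i, j] = m[i + dy, j + dx], FALSE outside
shift_mask <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  ri <- seq_len(h); ci <- seq_len(w)
  vr <- ri + dy >= 1L & ri + dy <= h
  vc <- ci + dx >= 1L & ci + dx <= w
  out[ri[vr], ci[vc]] <- m[ri[vr] + dy, ci[vc] + dx]
  out
}

disc_offsets <- function(radius) {
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# morphological opening by exhaustive shift-AND / shift-OR
oracle_opening <- function(m, radius) {
  if (radius == 0) return(m)
  offs <- disc_offsets(radius)
  ero <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offs)))
    ero <- ero & shift_mask(m, offs$dy[k], offs$dx[k])
  dil <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(offs)))
    dil <- dil | shift_mask(ero, offs$dy[k], offs$dx[k])
  dil
}

# 8-connected components by breadth-first flood fill
oracle_flood_fill <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  n <- 0L
  nbr_dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      r <- (cur - 1L) %% h + 1L
      cc <- (cur - 1L) %/% h + 1L
      for (k in 1:8) {
        rr <- r + nbr_dy[k]; ccc <- cc + nbr_dx[k]
        if (rr >= 1L && rr <= h && ccc >= 1L && ccc <= w) {
          idx <- (ccc - 1L) * h + rr
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- n
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  list(n = n, labels = lab)
}

# two labelings describe the same partition of the foreground
same_partition <- function(lab_a, lab_b) {
  fg <- lab_a > 0L
  if (!identical(fg, lab_b > 0L)) return(FALSE)
  key <- paste(lab_a[fg], lab_b[fg])
  length(unique(key)) == length(unique(lab_a[fg])) &&
    length(unique(key)) == length(unique(lab_b[fg]))
}

# textbook hexcone HSV for one pixel, written independently of rgb2hsv
oracle_hsb <- function(p) {
  r <- p[1] / 255; g <- p[2] / 255; b <- p[3] / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  s <- if (mx == 0) 0 else d / mx
  c(h = h, s = s, v = mx)
}

# uniform image of one color
uniform_image <- function(rgb, h = 8, w = 8) {
  image_rgb(array(rep(rgb, each = h * w), dim = c(h, w, 3L)))
}

random_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}
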