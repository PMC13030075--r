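# Independent oracles and scene builders used across the test files. These
# deliberately use naive loops / exhaustive enumeration, never the package's
# own code paths.

# Wrap a bare matrix as an elevation map (foreground = positive elevation).
make_elev <- function(values, foreground = values > 0) {
  structure(list(values = values, foreground = foreground,
                 background_level = 0),
            class = "elevation_map")
}

# Build a depth patch directly from a value matrix (bypasses normalization).
make_patch <- function(values) {
  stopifnot(nrow(values) == ncol(values), nrow(values) %% 2 == 1)
  structure(list(values = values, center = (nrow(values) + 1L) %/% 2L,
                 max_ring = (nrow(values) - 1L) %/% 2L,
                 marker = c(0L, 0L), degenerate = diff(range(values)) == 0),
            class = "depth_patch")
}

# Elevation field of one spherical cap (apex height h, radius R) on a flat
# plane, written without reusing the package generator.
cap_field <- function(H, W, row0, col0, R, h) {
  d2 <- outer((seq_len(H) - row0)^2, (seq_len(W) - col0)^2, `+`)
  v <- matrix(0, H, W)
  inside <- d2 <= R^2
  v[inside] <- h * sqrt(1 - d2[inside] / R^2)
  v
}

# Naive ring-level radial gradient profile: triple loop over rings, ring
# pixels, and 8-connected outer neighbors.
naive_radial_gradient <- function(values) {
  n <- nrow(values)
  ctr <- (n + 1L) %/% 2L
  max_ring <- (n - 1L) %/% 2L
  cheb_m <- outer(abs(seq_len(n) - ctr), abs(seq_len(n) - ctr), pmax)
  cheb <- function(r, c) cheb_m[r, c]
  res <- data.frame(r = integer(0), G = numeric(0), signed = numeric(0))
  for (r in seq_len(max_ring - 1L)) {
    ring_px <- which(cheb_m == r, arr.ind = TRUE)
    g_cl <- g_sg <- numeric(nrow(ring_px))
    for (k in seq_len(nrow(ring_px))) {
      pr <- ring_px[k, 1]; pc <- ring_px[k, 2]
      diffs <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        qr <- pr + dr; qc <- pc + dc
        if (qr < 1 || qr > n || qc < 1 || qc > n) next
        if (cheb(qr, qc) == r + 1L) {
          diffs <- c(diffs, values[pr, pc] - values[qr, qc])
        }
      }
      g_sg[k] <- mean(diffs)
      g_cl[k] <- max(0, g_sg[k])
    }
    res <- rbind(res, data.frame(r = r, G = mean(g_cl), signed = mean(g_sg)))
  }
  res
}

# Naive strided Gaussian window response: explicit double loop with mirror
# padding by index arithmetic.
naive_peak_response <- function(v, window, stride, sigma) {
  half <- (window - 1L) %/% 2L
  off <- seq.int(-half, half)
  k <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k <- k / sum(k)
  mirror <- function(i, n) {
    while (any(i < 1L | i > n)) {
      i <- ifelse(i < 1L, 2L - i, i)
      i <- ifelse(i > n, 2L * n - i, i)
    }
    i
  }
  gr <- seq.int(1L, nrow(v), by = stride)
  gc <- seq.int(1L, ncol(v), by = stride)
  out <- matrix(0, length(gr), length(gc))
  for (a in seq_along(gr)) {
    for (b in seq_along(gc)) {
      acc <- 0
      for (i in seq_along(off)) {
        for (j in seq_along(off)) {
          acc <- acc + k[i, j] * v[mirror(gr[a] + off[i], nrow(v)),
                                   mirror(gc[b] + off[j], ncol(v))]
        }
      }
      out[a, b] <- acc
    }
  }
  out
}

# Exhaustive best one-to-one assignment total over an IoU matrix (n <= 6),
# enumerating all injective row -> column maps.
brute_force_assignment_total <- function(iou, tau = 0) {
  nr <- nrow(iou); nc <- ncol(iou)
  best <- 0
  cols <- seq_len(nc)
  rec <- function(row, used, total) {
    if (row > nr) { best <<- max(best, total); return(invisible()) }
    rec(row + 1L, used, total)  # leave this row unmatched
    for (j in setdiff(cols, used)) {
      if (iou[row, j] >= tau && iou[row, j] > 0) {
        rec(row + 1L, c(used, j), total + iou[row, j])
      }
    }
  }
  rec(1L, integer(0), 0)
  best
}

# Brute-force Otsu threshold over all 256 candidate bin cuts of a [0,1] image.
brute_force_otsu <- function(g) {
  bins <- floor(g * 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  lv <- (0:255) / 255
  best_t <- NA; best_v <- -Inf
  for (t in 1:255) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * lv[1:t]) / w0
    m1 <- sum(p[(t + 1):256] * lv[(t + 1):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- lv[t] }
  }
  best_t
}

# Naive 3x3 correlation with replicate borders.
naive_convolve3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (dr in -1:1) for (dc in -1:1) {
        ri <- min(max(i + dr, 1L), nrow(m))
        ci <- min(max(j + dc, 1L), ncol(m))
        acc <- acc + k[dr + 2L, dc + 2L] * m[ri, ci]
      }
      out[i, j] <- acc
    }
  }
  out
}

# Small rectangular logical mask.
block_mask <- function(H, W, rows, cols) {
  m <- matrix(FALSE, H, W)
  m[rows, cols] <- TRUE
  m
}

# Standard multi-cap bed used by several end-to-end tests.
demo_bed_spec <- function(seed = 7) {
  caps <- data.frame(row = c(40, 40, 110, 110, 75),
                     col = c(40, 110, 40, 110, 75),
                     radius = c(8, 9, 10, 11, 9),
                     apex = c(6, 7, 8, 8, 7))
  scene_spec(150, 150, caps, depth_noise_sd = 0.1, seed = seed)
}

# Cojoined-pair bed: radius 12 so the 1.6R apex separation (19.2 px) clears
# the 18 px proximity suppression; compact region so the pair dominates the
# elevation histogram as in a dense bed.
cojoined_pair_spec <- function(seed = 3) {
  R <- 12; d <- 1.6 * R
  caps <- data.frame(row = c(24, 24), col = c(24 - d / 2, 24 + d / 2),
                     radius = R, apex = 8)
  scene_spec(48, 48, caps, depth_noise_sd = 0.05, seed = seed)
}
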