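# Internal helpers shared across modules. Images are base matrices indexed
# [row, col] (H x W, origin top-left, 1-based); color images are H x W x 3
# integer arrays in 0..255.

#' @importFrom rlang abort
NULL

stop_capseg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "capseg_error"))
}

#' Convert an RGB array to grayscale
#'
#' Standard luma weights (0.299, 0.587, 0.114). Accepts an H x W x 3 array on
#' any intensity scale; the output is on the same scale.
#'
#' @param rgb H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Reflect (mirror, without repeating the edge sample's neighbor policy of
# "symmetric" padding) index vector into 1..n.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  i <- (idx - 1L) %% period
  i <- ifelse(i < 0L, i + period, i)
  as.integer(ifelse(i < n, i + 1L, period - i + 1L))
}

# Pad a matrix by reflection on all sides.
pad_reflect <- function(m, top, bottom = top, left = top, right = top) {
  ri <- reflect_index(seq.int(1L - top, nrow(m) + bottom), nrow(m))
  ci <- reflect_index(seq.int(1L - left, ncol(m) + right), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Positions are clamped to the valid domain.
bilinear <- function(m, row, col) {
  H <- nrow(m); W <- ncol(m)
  row <- pmin(pmax(row, 1), H)
  col <- pmin(pmax(col, 1), W)
  r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
  if (H == 1L) r0 <- rep(1, length(row))
  if (W == 1L) c0 <- rep(1, length(col))
  fr <- row - r0; fc <- col - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc +
    m[cbind(r1, c1)] * fr * fc
}

# 8-connected component labeling of a logical matrix by iterative flood fill.
# EBImage::bwlabel is 4-connected, hence this small routine. Returns an
# integer matrix, 0 = background, components numbered in raster-scan order of
# their first pixel.
label_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      r <- ((p - 1L) %% H) + 1L
      cc <- ((p - 1L) %/% H) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cn <- cc + dc
        ok <- rr >= 1L & rr <= H & cn >= 1L & cn <= W
        if (!any(ok)) next
        q <- (cn[ok] - 1L) * H + rr[ok]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Min-max scale to [0, 1]; a constant input maps to all zeros (degenerate
# convention used throughout).
minmax01 <- function(m) {
  rng <- range(m)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= .Machine$double.eps) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1])
}

# Masks (logical matrices) -> list from a label map, names = label ids.
label_map_to_masks <- function(labels) {
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  out <- lapply(ids, function(id) labels == id)
  names(out) <- as.character(ids)
  out
}

masks_to_label_map <- function(masks, shape, ids = seq_along(masks)) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(masks)) lab[masks[[i]]] <- as.integer(ids[i])
  lab
}
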