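#' Gaussian-weighted strided peak response
#'
#' Slides a Gaussian-weighted `window` x `window` kernel (normalized to sum 1)
#' over the elevation map at the given stride, with reflect padding at the
#' borders. Each output cell emphasizes central high-elevation pixels while
#' suppressing shallow compost-surface variation.
#'
#' @param elev An `elevation_map` or an H x W numeric matrix.
#' @param window Odd window side (default from config: 5).
#' @param stride Stride in pixels (default 3).
#' @param sigma Gaussian sigma of the weights (default 1.1).
#' @return A list with `response` (reduced-grid matrix), `grid_rows`,
#'   `grid_cols` (full-resolution row/col of each grid center).
#' @export
peak_response <- function(elev, window = 5, stride = 3, sigma = 1.1) {
  v <- if (inherits(elev, "elevation_map")) elev$values else elev
  stopifnot(window %% 2 == 1, stride >= 1)
  if (window > nrow(v) || window > ncol(v)) {
    stop_capseg("window larger than image", "capseg_dimension_error")
  }
  half <- (window - 1L) %/% 2L
  off <- seq.int(-half, half)
  k <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k <- k / sum(k)
  padded <- pad_reflect(v, half)
  grid_rows <- seq.int(1L, nrow(v), by = stride)
  grid_cols <- seq.int(1L, ncol(v), by = stride)
  resp <- matrix(0, length(grid_rows), length(grid_cols))
  for (i in seq_along(grid_rows)) {
    for (j in seq_along(grid_cols)) {
      r0 <- grid_rows[i]  # padded offset: +half shifts, window starts at r0
      c0 <- grid_cols[j]
      resp[i, j] <- sum(padded[r0:(r0 + window - 1L),
                               c0:(c0 + window - 1L)] * k)
    }
  }
  list(response = resp, grid_rows = grid_rows, grid_cols = grid_cols)
}

# Brute-force bilateral filter on a small matrix. Values are expected in
# normalized [0,1] units.
bilateral_filter <- function(m, d = 9, sigma_space = 5, sigma_range = 0.1) {
  stopifnot(d %% 2 == 1)
  half <- (d - 1L) %/% 2L
  off <- seq.int(-half, half)
  sw <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma_space^2)))
  padded <- pad_reflect(m, half)
  out <- m
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      nb <- padded[i:(i + d - 1L), j:(j + d - 1L)]
      w <- sw * exp(-(nb - m[i, j])^2 / (2 * sigma_range^2))
      out[i, j] <- sum(w * nb) / sum(w)
    }
  }
  out
}

#' Detect candidate cap-apex markers from an elevation map
#'
#' The strided Gaussian peak response is smoothed by a bilateral filter,
#' binarized above a high-elevation quantile, and segmented into 8-connected
#' components. Each component contributes one marker: the full-resolution
#' pixel of maximal elevation within the component's footprint. Markers closer
#' than `proximity_px` to a stronger (higher-elevation) marker are suppressed.
#'
#' @param elev An `elevation_map`.
#' @param config A [pipeline_config()].
#' @return A tibble of class `capseg_markers` with columns `row`, `col`
#'   (1-based full-resolution pixel), `elevation`; the reduced-grid response is
#'   attached as attribute `response`.
#' @export
detect_markers <- function(elev, config = pipeline_config()) {
  v <- elev$values
  pr <- peak_response(v, config$marker_window, config$marker_stride,
                      config$marker_sigma)
  resp <- bilateral_filter(pr$response, config$bilateral_d,
                           config$bilateral_sigma_space,
                           config$bilateral_sigma_range)
  thr <- stats::quantile(resp, config$response_quantile, names = FALSE)
  high <- resp > thr
  empty <- tibble::tibble(row = integer(0), col = integer(0),
                          elevation = numeric(0))
  if (!any(high)) {
    return(structure(empty, response = resp,
                     class = c("capseg_markers", class(empty))))
  }
  comp <- label_components8(high)
  half_block <- config$marker_stride %/% 2L
  cand <- purrr::map_dfr(seq_len(max(comp)), function(id) {
    cells <- which(comp == id, arr.ind = TRUE)
    # footprint: union of stride-blocks centered on the member grid cells
    rows <- integer(0); cols <- integer(0)
    px <- matrix(0L, 0, 2)
    for (k in seq_len(nrow(cells))) {
      rc <- pr$grid_rows[cells[k, 1]]
      cc <- pr$grid_cols[cells[k, 2]]
      rr <- max(1L, rc - half_block):min(nrow(v), rc + half_block)
      cr <- max(1L, cc - half_block):min(ncol(v), cc + half_block)
      px <- rbind(px, as.matrix(expand.grid(rr, cr)))
    }
    px <- unique(px)
    vals <- v[px]
    best <- which.max(vals)
    tibble::tibble(row = as.integer(px[best, 1]), col = as.integer(px[best, 2]),
                   elevation = vals[best])
  })
  cand <- dplyr::arrange(cand, dplyr::desc(.data$elevation))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    dist2 <- (kept$row - cand$row[i])^2 + (kept$col - cand$col[i])^2
    keep[i] <- all(dist2 > config$proximity_px^2)
  }
  out <- cand[keep, ]
  structure(out, response = resp,
            class = c("capseg_markers", class(empty)))
}
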