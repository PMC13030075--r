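#' Per-pixel coverage count over a set of instance masks
#'
#' @param masks List of H x W logical matrices.
#' @return H x W integer matrix; `counts(p)` is the number of masks containing
#'   pixel p. Values >= 2 mark contested (overlapping) regions.
#' @export
coverage_count <- function(masks) {
  stopifnot(length(masks) >= 1L)
  dims <- dim(masks[[1]])
  counts <- matrix(0L, dims[1], dims[2])
  for (m in masks) {
    stopifnot(all(dim(m) == dims))
    counts <- counts + m
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Sobel gradient-magnitude ridge map of an elevation map
#'
#' The elevation surface is pre-smoothed with a Gaussian (sigma from config)
#' to suppress depth noise, then the Sobel gradient magnitude
#' `sqrt(gx^2 + gy^2)` is computed. Ridges (high values) sit on cap
#' boundaries and halt watershed growth.
#'
#' @param elev An `elevation_map` or numeric matrix.
#' @param sigma Gaussian pre-smoothing sigma in pixels. Default 1.
#' @return H x W non-negative matrix.
#' @export
ridge_map <- function(elev, sigma = 1) {
  v <- if (inherits(elev, "elevation_map")) elev$values else elev
  sm <- as.matrix(EBImage::gblur(EBImage::Image(v), sigma = sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- sobel_convolve(sm, kx)
  gy <- sobel_convolve(sm, t(kx))
  sqrt(gx^2 + gy^2)
}

# Correlation with a 3x3 kernel, replicate borders.
sobel_convolve <- function(m, k) {
  p <- pad_replicate(m, 1L)
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + k[dr + 2L, dc + 2L] *
      p[(2L + dr):(nrow(m) + 1L + dr), (2L + dc):(ncol(m) + 1L + dc)]
  }
  out
}

pad_replicate <- function(m, k) {
  ri <- pmin(pmax(seq.int(1L - k, nrow(m) + k), 1L), nrow(m))
  ci <- pmin(pmax(seq.int(1L - k, ncol(m) + k), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resolve multiply-claimed pixels with a depth-guided marker-controlled watershed
#'
#' Pixels claimed by exactly one instance keep their owner. For contested
#' pixels (coverage >= 2), each involved instance seeds from its confidently
#' owned interior (its exclusively-owned region eroded with a 3x3 box,
#' `seed_erode_iters` times; fallback: its single maximal-elevation exclusive
#' pixel), and marker-controlled region growth over the Sobel ridge map
#' assigns every contested pixel to exactly one instance. Minor morphological
#' cleanup follows: per-instance speck removal (8-connected components smaller
#' than `speck_min_px`) and hole filling (holes are claimed only from
#' background so the one-owner guarantee is preserved). An instance left with
#' no seed loses its contested pixels to competitors; an instance left with
#' zero pixels is dropped.
#'
#' @param masks Named list of H x W logical instance masks (names = ids), or a
#'   `capseg_segmentation`.
#' @param elev An `elevation_map`.
#' @param config A [pipeline_config()].
#' @return Integer label map (provenance "resolved"): 0 = background, one
#'   unique id per instance; attribute `dropped` lists ids that vanished.
#' @export
resolve_overlaps <- function(masks, elev, config = pipeline_config()) {
  if (inherits(masks, "capseg_segmentation")) masks <- masks$masks
  if (!length(masks)) {
    out <- matrix(0L, nrow(elev$values), ncol(elev$values))
    attr(out, "provenance") <- "resolved"
    return(out)
  }
  ids <- names(masks)
  if (is.null(ids)) ids <- as.character(seq_along(masks))
  ids_num <- as.integer(ids)
  ord <- order(ids_num)  # deterministic: ids ascending
  masks <- masks[ord]; ids_num <- ids_num[ord]
  shape <- dim(masks[[1]])
  counts <- coverage_count(masks)
  labels <- matrix(0L, shape[1], shape[2])
  exclusive <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    excl <- masks[[i]] & counts == 1L
    labels[excl] <- ids_num[i]
    exclusive[[i]] <- excl
  }
  contested <- counts >= 2L
  if (any(contested)) {
    ridge <- ridge_map(elev, config$ridge_sigma)
    brush <- EBImage::makeBrush(3L, shape = "box")
    seeds <- matrix(0L, shape[1], shape[2])
    for (i in seq_along(masks)) {
      core <- exclusive[[i]]
      if (any(core)) {
        er <- core
        for (it in seq_len(config$seed_erode_iters)) {
          er2 <- as.matrix(EBImage::erode(EBImage::Image(er * 1), brush)) > 0.5
          if (!any(er2)) break
          er <- er2
        }
        if (!any(er)) {
          # fallback: single maximal-elevation exclusively-owned pixel
          vals <- elev$values
          vals[!core] <- -Inf
          er <- matrix(FALSE, shape[1], shape[2])
          er[which.max(vals)] <- TRUE
        }
        seeds[er] <- ids_num[i]
      }
    }
    if (any(seeds > 0L)) {
      region <- contested | seeds > 0L
      grown <- EBImage::propagate(EBImage::Image(ridge),
                                  EBImage::Image(seeds),
                                  mask = EBImage::Image(region * 1))
      grown <- matrix(as.integer(grown), shape[1], shape[2])
      labels[contested] <- grown[contested]
    }
    # contested pixels of seedless instances may remain 0; leave as background
  }
  # cleanup: speck removal then hole filling, per instance
  for (i in seq_along(masks)) {
    id <- ids_num[i]
    inst <- labels == id
    if (!any(inst)) next
    comp <- label_components8(inst)
    sizes <- tabulate(comp[comp > 0L])
    small <- which(sizes < config$speck_min_px)
    if (length(small) && length(small) < length(sizes)) {
      labels[inst & comp %in% small] <- 0L
    } else if (length(small) == length(sizes) && length(sizes) > 0L &&
               max(sizes) < config$speck_min_px) {
      labels[inst] <- 0L  # whole instance is specks -> dropped
      next
    }
    inst <- labels == id
    if (!any(inst)) next
    filled <- as.matrix(EBImage::fillHull(EBImage::Image(inst * 1))) > 0.5
    claim <- filled & !inst & labels == 0L
    labels[claim] <- id
  }
  dropped <- ids_num[!ids_num %in% unique(as.integer(labels))]
  attr(labels, "provenance") <- "resolved"
  attr(labels, "dropped") <- dropped
  labels
}
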