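#' Extract and normalize the per-marker elevation patch
#'
#' Crops a `patch_size` x `patch_size` window centered on the marker (reflect
#' padding when the marker sits near the image border) and min-max normalizes
#' it within the patch. A constant patch normalizes to all zeros by convention
#' and is discarded upstream (a flat patch cannot be a cap).
#'
#' @param elev An `elevation_map` or numeric matrix.
#' @param marker Length-2 integer vector `(row, col)`, 1-based.
#' @param patch_size Odd patch side (default 23).
#' @return An object of class `depth_patch`: list with `values`
#'   (patch matrix in \[0,1\]), `center` (index of the central pixel),
#'   `max_ring`, `marker` (image coordinates), `degenerate` flag.
#' @export
extract_patch <- function(elev, marker, patch_size = 23) {
  v <- if (inherits(elev, "elevation_map")) elev$values else elev
  stopifnot(patch_size %% 2 == 1)
  r <- marker[1]; cc <- marker[2]
  if (r < 1 || r > nrow(v) || cc < 1 || cc > ncol(v)) {
    stop_capseg("marker outside image", "capseg_dimension_error")
  }
  half <- (patch_size - 1L) %/% 2L
  ri <- reflect_index(seq.int(r - half, r + half), nrow(v))
  ci <- reflect_index(seq.int(cc - half, cc + half), ncol(v))
  raw <- v[ri, ci, drop = FALSE]
  rng <- range(raw)
  degenerate <- rng[2] - rng[1] <= .Machine$double.eps
  structure(list(values = minmax01(raw), center = half + 1L,
                 max_ring = half, marker = c(r, cc), degenerate = degenerate),
            class = "depth_patch")
}

# Chebyshev ring r pixel offsets (dr, dc) around the patch center; 8r pixels.
ring_offsets <- function(r) {
  if (r == 0L) return(matrix(0L, 1, 2))
  top <- cbind(-r, seq.int(-r, r))
  bottom <- cbind(r, seq.int(-r, r))
  left <- cbind(seq.int(-r + 1L, r - 1L), -r)
  right <- cbind(seq.int(-r + 1L, r - 1L), r)
  rbind(top, bottom, left, right)
}

#' Radial gradient profile of a patch (ring-level)
#'
#' For each ring `r = 1..max_ring-1`, every pixel p on the Chebyshev square
#' B(r) is compared with its 8-connected neighbors lying on B(r+1): the
#' pixelwise gradient is `max(0, mean(D(p) - D(q)))` (descending height
#' transitions only; negative gradients caused by an adjacent overlapping cap
#' are suppressed), and `G(r)` averages the pixelwise gradients over the K
#' ring pixels. The unclamped (`signed`) profile is recorded alongside for
#' overlap detection.
#'
#' @param patch A `depth_patch`.
#' @return A tibble of class `capseg_radial_profile` with columns `r`, `G`
#'   (clamped, non-negative), `signed`, `K`.
#' @export
radial_gradient <- function(patch) {
  v <- patch$values
  ctr <- patch$center
  out <- purrr::map_dfr(seq_len(patch$max_ring - 1L), function(r) {
    px <- ring_offsets(r)
    grads <- clamped <- numeric(nrow(px))
    for (k in seq_len(nrow(px))) {
      pr <- ctr + px[k, 1]; pc <- ctr + px[k, 2]
      nb <- expand.grid(dr = -1:1, dc = -1:1)
      nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
      qr <- pr + nb$dr; qc <- pc + nb$dc
      on_outer <- pmax(abs(qr - ctr), abs(qc - ctr)) == r + 1L &
        qr >= 1L & qr <= nrow(v) & qc >= 1L & qc <= ncol(v)
      diffs <- v[pr, pc] - v[cbind(qr[on_outer], qc[on_outer])]
      grads[k] <- mean(diffs)
      clamped[k] <- max(0, grads[k])
    }
    tibble::tibble(r = r, G = mean(clamped), signed = mean(grads),
                   K = nrow(px))
  })
  structure(out, class = c("capseg_radial_profile", class(out)))
}

# Directional elevation profile d(0..max_ring) along angle theta by bilinear
# sampling at Euclidean radii.
ray_profile <- function(patch, theta) {
  r <- 0:patch$max_ring
  bilinear(patch$values,
           patch$center + r * sin(theta),
           patch$center + r * cos(theta))
}

#' Cojoined-cap boundary limit along one direction
#'
#' Walks the directional elevation profile outward from the patch center and
#' returns the first radius at which the surface starts rising again after
#' descending (an inflection in the signed radial change: the onset of an
#' adjacent cap). Returns `max_ring` when the profile never turns upward; a
#' profile rising immediately from the center returns 1 (clamped minimum).
#'
#' @param patch A `depth_patch`.
#' @param theta Direction in radians.
#' @param rise_eps Minimum upward step treated as a rise (guards against
#'   floating-point jitter on flat compost). Default 1e-9.
#' @return Integer limit radius in 1..max_ring.
#' @export
overlap_limit <- function(patch, theta, rise_eps = 1e-9) {
  d <- ray_profile(patch, theta)
  steps <- diff(d)  # steps[r] = d(r) - d(r-1), r = 1..max_ring
  up <- which(steps > rise_eps)
  if (!length(up)) return(patch$max_ring)
  max(1L, up[1] - 1L)
}

#' First-pass boundary candidates by per-ray gradient peaks
#'
#' For each of `n_rays` equally spaced directions the directional gradient
#' `g(r) = d(r-1) - d(r)` (the elevation drop into ring r, clamped at 0 for
#' peak ranking) is computed over rings within that ray's [overlap_limit()].
#' The ring of highest gradient is the primary boundary candidate, the second
#' highest the backup; equal gradients break toward the smaller radius
#' (conservative cap extent). Rays with no positive drop contribute no point;
#' a flat (degenerate) patch yields an empty set.
#'
#' @param patch A `depth_patch`.
#' @param config A [pipeline_config()].
#' @return A tibble of class `capseg_boundary` with columns `theta`,
#'   `primary_r`, `primary_g`, `backup_r`, `backup_g` (NA when absent),
#'   `limit`.
#' @export
trace_boundary <- function(patch, config = pipeline_config()) {
  empty <- tibble::tibble(theta = numeric(0), primary_r = numeric(0),
                          primary_g = numeric(0), backup_r = numeric(0),
                          backup_g = numeric(0), limit = integer(0))
  if (patch$degenerate) {
    return(structure(empty, class = c("capseg_boundary", class(empty))))
  }
  thetas <- seq(0, 2 * pi, length.out = config$n_rays + 1L)[-(config$n_rays + 1L)]
  rows <- purrr::map_dfr(thetas, function(th) {
    d <- ray_profile(patch, th)
    steps <- diff(d)
    up <- which(steps > 1e-9)
    limit <- if (!length(up)) patch$max_ring else max(1L, up[1] - 1L)
    g <- pmax(0, -steps[seq_len(limit)])  # drop into ring r, r = 1..limit
    if (!any(g > 0)) return(NULL)
    ord <- order(-g, seq_along(g))  # ties -> smaller radius
    primary <- ord[1]
    backup <- if (length(ord) > 1L && g[ord[2]] > 0) ord[2] else NA_integer_
    tibble::tibble(theta = th,
                   primary_r = primary, primary_g = g[primary],
                   backup_r = backup,
                   backup_g = if (is.na(backup)) NA_real_ else g[backup],
                   limit = as.integer(limit))
  })
  if (is.null(rows) || !nrow(rows)) rows <- empty
  structure(rows, class = c("capseg_boundary", class(empty)))
}

#' Two-pass boundary refinement
#'
#' Pass 2 (local consistency): each point's radius is compared with the mean
#' radius of its `neighbor_count` contour neighbors (half on each side in
#' angular order, wrapping at 0/2pi); a point deviating by more than
#' `local_dev_px` is replaced by its backup candidate if the backup passes the
#' same check, otherwise dropped. Pass 3 (centroid-based global adjustment):
#' the centroid of surviving points is computed, then the mean and standard
#' deviation of point-to-centroid distances; points deviating from the mean by
#' more than `global_sd_mult` standard deviations are removed. Passes always
#' run in that order.
#'
#' @param points A `capseg_boundary` tibble from [trace_boundary()].
#' @param config A [pipeline_config()].
#' @return The surviving points (same class), with the chosen radius in
#'   column `r`.
#' @export
refine_boundary <- function(points, config = pipeline_config()) {
  if (nrow(points) < 3L) {
    stop_capseg("fewer than 3 boundary points: degenerate contour",
                "capseg_degenerate_error")
  }
  pts <- dplyr::arrange(points, .data$theta)
  n <- nrow(pts)
  half <- max(1L, config$neighbor_count %/% 2L)
  radius <- pts$primary_r
  local_mean <- vapply(seq_len(n), function(i) {
    nb <- c(i - half:1, i + 1:half)
    nb <- ((nb - 1L) %% n) + 1L
    nb <- setdiff(nb, i)
    mean(radius[nb])
  }, numeric(1))
  chosen <- radius
  ok <- abs(radius - local_mean) <= config$local_dev_px
  for (i in which(!ok)) {
    b <- pts$backup_r[i]
    if (!is.na(b) && abs(b - local_mean[i]) <= config$local_dev_px) {
      chosen[i] <- b
      ok[i] <- TRUE
    }
  }
  pts <- pts[ok, , drop = FALSE]
  chosen <- chosen[ok]
  if (nrow(pts) < 3L) {
    stop_capseg("fewer than 3 points survive local consistency filtering",
                "capseg_degenerate_error")
  }
  # Pass 3: centroid-based global adjustment
  x <- chosen * cos(pts$theta)
  y <- chosen * sin(pts$theta)
  cx <- mean(x); cy <- mean(y)
  dist <- sqrt((x - cx)^2 + (y - cy)^2)
  sd_d <- stats::sd(dist)
  # an (effectively) zero spread removes nothing
  keep <- if (is.na(sd_d) || sd_d <= 1e-9) rep(TRUE, length(dist)) else
    abs(dist - mean(dist)) <= config$global_sd_mult * sd_d
  pts <- pts[keep, , drop = FALSE]
  chosen <- chosen[keep]
  if (nrow(pts) < 3L) {
    stop_capseg("fewer than 3 points survive global adjustment",
                "capseg_degenerate_error")
  }
  pts$r <- chosen
  pts
}

#' Rasterize refined boundary points as a convex-hull instance mask
#'
#' The points (translated to image coordinates around the marker) are closed
#' into a convex hull, the hull polygon is filled, and the fill is intersected
#' with the color-derived Otsu foreground so compost background is excluded.
#'
#' @param points Refined boundary tibble (needs `theta` and `r`).
#' @param marker `(row, col)` of the owning marker.
#' @param rgb_foreground H x W logical foreground mask (or NULL to skip the
#'   intersection).
#' @param shape `c(H, W)` of the output mask.
#' @return H x W logical instance mask.
#' @export
points_to_mask <- function(points, marker, rgb_foreground, shape) {
  if (nrow(points) < 3L) {
    stop_capseg("need at least 3 points for a hull", "capseg_degenerate_error")
  }
  rr <- marker[1] + points$r * sin(points$theta)
  cc <- marker[2] + points$r * cos(points$theta)
  hull_idx <- grDevices::chull(cc, rr)
  if (length(hull_idx) < 3L) {
    stop_capseg("collinear boundary points: degenerate hull",
                "capseg_degenerate_error")
  }
  hx <- cc[hull_idx]; hy <- rr[hull_idx]
  # signed area to fix orientation
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (abs(area2) < 1e-9) {
    stop_capseg("collinear boundary points: degenerate hull",
                "capseg_degenerate_error")
  }
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  r0 <- max(1L, floor(min(rr))); r1 <- min(shape[1], ceiling(max(rr)))
  c0 <- max(1L, floor(min(cc))); c1 <- min(shape[2], ceiling(max(cc)))
  mask <- matrix(FALSE, shape[1], shape[2])
  if (r1 >= r0 && c1 >= c0) {
    grid <- expand.grid(row = r0:r1, col = c0:c1)
    inside <- rep(TRUE, nrow(grid))
    nh <- length(hx)
    for (e in seq_len(nh)) {
      e2 <- if (e == nh) 1L else e + 1L
      # counter-clockwise polygon: interior has non-negative cross products
      cr <- (hx[e2] - hx[e]) * (grid$row - hy[e]) -
        (hy[e2] - hy[e]) * (grid$col - hx[e])
      inside <- inside & cr >= -1e-9
    }
    mask[cbind(grid$row[inside], grid$col[inside])] <- TRUE
  }
  if (!is.null(rgb_foreground)) mask <- mask & rgb_foreground
  mask
}

#' Segment every marker in one frame into raw (possibly overlapping) masks
#'
#' Runs patch extraction, radial gradient tracing, overlap limiting, two-pass
#' refinement and hull rasterization per marker. Masks may overlap where caps
#' touch; overlap is resolved downstream by [resolve_overlaps()]. Markers with
#' degenerate patches or contours are dropped (recorded in the `dropped`
#' attribute).
#'
#' @param elev An `elevation_map`.
#' @param rgb_foreground H x W logical Otsu foreground.
#' @param markers A `capseg_markers` tibble.
#' @param config A [pipeline_config()].
#' @return A list of class `capseg_segmentation`: `masks` (named list of
#'   logical matrices, one per surviving marker), `markers` (their rows),
#'   `boundaries` (list of refined point tibbles), `labels` (raw-hulls label
#'   map where later instances overwrite earlier in ties — use
#'   [resolve_overlaps()] for the resolved map), `dropped` (indices).
#' @export
segment_frame <- function(elev, rgb_foreground, markers,
                          config = pipeline_config()) {
  shape <- dim(elev$values)
  masks <- list(); bounds <- list(); kept <- integer(0); dropped <- integer(0)
  for (i in seq_len(nrow(markers))) {
    mk <- c(markers$row[i], markers$col[i])
    res <- tryCatch({
      patch <- extract_patch(elev, mk, config$patch_size)
      if (patch$degenerate) stop_capseg("flat patch", "capseg_degenerate_error")
      pts <- trace_boundary(patch, config)
      if (nrow(pts) < 3L) stop_capseg("too few points",
                                      "capseg_degenerate_error")
      ref <- refine_boundary(pts, config)
      mask <- points_to_mask(ref, mk, rgb_foreground, shape)
      if (!any(mask)) stop_capseg("empty mask", "capseg_degenerate_error")
      list(mask = mask, pts = ref)
    }, capseg_degenerate_error = function(e) NULL)
    if (is.null(res)) {
      dropped <- c(dropped, i)
    } else {
      kept <- c(kept, i)
      masks[[length(masks) + 1L]] <- res$mask
      bounds[[length(bounds) + 1L]] <- res$pts
    }
  }
  names(masks) <- as.character(seq_along(masks))
  labels <- masks_to_label_map(masks, shape)
  structure(list(masks = masks, markers = markers[kept, , drop = FALSE],
                 boundaries = bounds, labels = labels, dropped = dropped,
                 provenance = "raw-hulls"),
            class = "capseg_segmentation")
}

#' @export
print.capseg_segmentation <- function(x, ...) {
  cat(sprintf("<capseg_segmentation: %d instance(s), %d dropped, %s>\n",
              length(x$masks), length(x$dropped), x$provenance))
  invisible(x)
}
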