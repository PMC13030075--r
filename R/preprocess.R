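#' Otsu foreground mask from a color image
#'
#' The color image is converted to grayscale and thresholded at the value
#' maximizing between-class variance over a 256-bin histogram; the foreground
#' is the side with the higher mean intensity (mushroom caps are light against
#' dark compost).
#'
#' @param rgb H x W x 3 array, intensities 0-255.
#' @return H x W logical matrix, TRUE = foreground.
#' @export
otsu_foreground <- function(rgb) {
  g <- rgb_to_gray(rgb) / 255
  if (diff(range(g)) <= .Machine$double.eps) {
    stop_capseg("constant image: Otsu histogram is degenerate",
                "capseg_degenerate_error")
  }
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1), levels = 256)
  hi <- g > thr
  if (!any(hi) || !all(hi)) {
    mean_hi <- mean(g[hi]); mean_lo <- mean(g[!hi])
    if (mean_lo > mean_hi) hi <- !hi
  }
  hi
}

#' Background homogenization and elevation normalization
#'
#' All valid background (non-foreground) depth pixels are averaged and every
#' background or missing-depth pixel is reassigned that mean, flattening the
#' compost plane. Missing depth inside the foreground is filled by an iterated
#' 3x3 median of valid neighbors. Depth from the camera is then converted to
#' elevation above the compost (`background_level - depth`, so cap apices are
#' maxima) and min-max scaled to \[0, 1\].
#'
#' @param depth H x W depth matrix (sensor units, larger = farther).
#' @param foreground H x W logical matrix from [otsu_foreground()].
#' @param missing Optional H x W logical matrix of invalid depth pixels.
#' @return An object of class `elevation_map`: list with `values` (H x W in
#'   \[0,1\]), `foreground`, and `background_level` (sensor units).
#' @export
homogenize_background <- function(depth, foreground, missing = NULL) {
  stopifnot(is.matrix(depth), all(dim(depth) == dim(foreground)))
  if (is.null(missing)) missing <- matrix(FALSE, nrow(depth), ncol(depth))
  h <- homogenize_depth(depth, foreground, missing)
  elev <- h$background_level - h$depth
  structure(list(values = minmax01(elev), foreground = foreground,
                 background_level = h$background_level),
            class = "elevation_map")
}

# Idempotent depth-space step: flatten the background to its mean and fill
# missing foreground depth by iterated 3x3 median of valid neighbors.
homogenize_depth <- function(depth, foreground, missing) {
  bg_valid <- !foreground & !missing
  if (!any(bg_valid)) {
    stop_capseg("no valid background pixel to homogenize against",
                "capseg_homogenization_error")
  }
  bg_level <- mean(depth[bg_valid])
  d <- depth
  d[!foreground] <- bg_level
  miss_fg <- missing & foreground
  guard <- 0L
  while (any(miss_fg) && guard < 64L) {
    guard <- guard + 1L
    idx <- which(miss_fg, arr.ind = TRUE)
    filled <- rep(NA_real_, nrow(idx))
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; cc <- idx[i, 2]
      rr <- max(1L, r - 1L):min(nrow(d), r + 1L)
      cr <- max(1L, cc - 1L):min(ncol(d), cc + 1L)
      # valid *foreground* neighbors only: the flattened background would
      # otherwise bleed into cap edges
      vals <- d[rr, cr][foreground[rr, cr] & !miss_fg[rr, cr]]
      if (length(vals)) filled[i] <- stats::median(vals)
    }
    ok <- !is.na(filled)
    if (!any(ok)) break
    d[idx[ok, , drop = FALSE]] <- filled[ok]
    miss_fg[idx[ok, , drop = FALSE]] <- FALSE
  }
  if (any(miss_fg)) d[miss_fg] <- bg_level
  list(depth = d, background_level = bg_level)
}

#' Preprocess one RGB-D frame into an elevation map
#'
#' Convenience wrapper: [otsu_foreground()] on the color image, then
#' [homogenize_background()] on the depth.
#'
#' @param frame An [rgbd_frame()].
#' @param config A [pipeline_config()] (unused here, accepted for interface
#'   symmetry).
#' @return An `elevation_map`.
#' @export
preprocess_frame <- function(frame, config = pipeline_config()) {
  fg <- otsu_foreground(frame$rgb)
  homogenize_background(frame$depth, fg, frame$missing)
}

#' @export
print.elevation_map <- function(x, ...) {
  cat(sprintf(
    "<elevation_map %d x %d, %.1f%% foreground, background level %.3f>\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$foreground),
    x$background_level))
  invisible(x)
}
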