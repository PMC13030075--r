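#' Vertical offset between two overlapping frames by template matching
#'
#' A template of the bottom `template_height` rows of `prev` is slid over every
#' vertical placement of `next_frame` (horizontal lag fixed at 0: the camera
#' moves on a one-dimensional rail) and scored by normalized cross-correlation
#' of the grayscale images. The best placement `y_offset` is the 0-based row in
#' `next_frame` where the template's top edge lands.
#'
#' @param prev,next_frame [rgbd_frame()]s of equal width.
#' @param template_height Template height in rows.
#' @return A list with `y_offset` (0-based row), `score` in \[-1, 1\], and
#'   `low_confidence` (TRUE when score < 0.5).
#' @export
match_offset <- function(prev, next_frame,
                         template_height = pipeline_config()$template_height_px) {
  g_prev <- rgb_to_gray(prev$rgb)
  g_next <- rgb_to_gray(next_frame$rgb)
  H <- nrow(g_prev)
  if (ncol(g_prev) != ncol(g_next)) {
    stop_capseg("frames must share width for stitching",
                "capseg_dimension_error")
  }
  if (template_height > H || template_height > nrow(g_next)) {
    stop_capseg("template taller than frame", "capseg_dimension_error")
  }
  templ <- g_prev[(H - template_height + 1L):H, , drop = FALSE]
  tv <- as.vector(templ)
  tv <- tv - mean(tv)
  tnorm <- sqrt(sum(tv^2))
  n_place <- nrow(g_next) - template_height + 1L
  scores <- vapply(seq_len(n_place), function(y) {
    wv <- as.vector(g_next[y:(y + template_height - 1L), , drop = FALSE])
    wv <- wv - mean(wv)
    wnorm <- sqrt(sum(wv^2))
    if (tnorm == 0 || wnorm == 0) return(-Inf)
    sum(tv * wv) / (tnorm * wnorm)
  }, numeric(1))
  best <- which.max(scores)
  score <- scores[best]
  list(y_offset = best - 1L,
       score = if (is.finite(score)) score else NA_real_,
       low_confidence = !is.finite(score) || score < 0.5)
}

#' Effective overlap ratio of a stitched frame pair
#'
#' The overlap height is `template_height + y_offset` and the ratio is that
#' height divided by the frame height. With the rail geometry used to acquire
#' bed mosaics (template 100 px, offset 561 px, frames 720 px tall) the ratio
#' is approximately 0.918.
#'
#' @param y_offset Matched vertical offset (0-based pixels).
#' @param template_height Template height in pixels.
#' @param frame_height Frame height in pixels.
#' @return Overlap ratio in \[0, 1\].
#' @export
overlap_ratio <- function(y_offset, template_height, frame_height) {
  stopifnot(y_offset >= 0, template_height > 0, frame_height > 0)
  if (y_offset + template_height > frame_height) {
    stop_capseg("y_offset + template_height exceeds frame height",
                "capseg_dimension_error")
  }
  (template_height + y_offset) / frame_height
}

#' Stitch a sequence of vertically overlapping frames into one mosaic
#'
#' Each consecutive pair is aligned with [match_offset()] on the color images;
#' only the non-overlapping bottom rows of the later frame are appended (hard
#' cut, no blending), and the same color-derived offset is applied to the depth
#' maps so the color and depth mosaics stay pixel-aligned.
#'
#' @param frames List of [rgbd_frame()]s of equal width.
#' @param config A [pipeline_config()] (template height, score floor).
#' @return A list of class `capseg_stitch` with elements `mosaic`
#'   ([rgbd_frame()]), `offsets` (integer vector, length n-1),
#'   `overlap_ratios`, and `scores`.
#' @export
stitch_sequence <- function(frames, config = pipeline_config()) {
  stopifnot(length(frames) >= 1L)
  ht <- config$template_height_px
  mosaic_rgb <- frames[[1]]$rgb
  mosaic_depth <- frames[[1]]$depth
  mosaic_missing <- frames[[1]]$missing
  offsets <- integer(0); ratios <- numeric(0); scores <- numeric(0)
  for (i in seq_along(frames)[-1]) {
    prev <- frames[[i - 1L]]
    nxt <- frames[[i]]
    m <- match_offset(prev, nxt, ht)
    if (m$low_confidence || m$score < config$stitch_score_floor) {
      stop_capseg(sprintf(
        "stitching failed between frames %d and %d (score %.3f < %.2f)",
        i - 1L, i, m$score, config$stitch_score_floor),
        "capseg_stitch_error")
    }
    h_overlap <- ht + m$y_offset
    H <- nrow(nxt$depth)
    offsets <- c(offsets, m$y_offset)
    ratios <- c(ratios, overlap_ratio(m$y_offset, ht, H))
    scores <- c(scores, m$score)
    if (h_overlap < H) {
      keep <- (h_overlap + 1L):H
      mosaic_rgb <- abind_rows(mosaic_rgb, nxt$rgb[keep, , , drop = FALSE])
      mosaic_depth <- rbind(mosaic_depth, nxt$depth[keep, , drop = FALSE])
      mosaic_missing <- rbind(mosaic_missing, nxt$missing[keep, , drop = FALSE])
    }
  }
  structure(list(
    mosaic = rgbd_frame(mosaic_rgb, mosaic_depth, mosaic_missing,
                        frames[[1]]$frame_index),
    offsets = offsets, overlap_ratios = ratios, scores = scores),
    class = "capseg_stitch")
}

# rbind for H x W x 3 arrays along rows.
abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], 3L))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' @export
print.capseg_stitch <- function(x, ...) {
  cat(sprintf("<capseg_stitch: mosaic %d x %d from %d frame(s)>\n",
              nrow(x$mosaic$depth), ncol(x$mosaic$depth),
              length(x$offsets) + 1L))
  if (length(x$offsets)) {
    cat("  offsets:", paste(x$offsets, collapse = ", "), "\n")
    cat("  overlap ratios:",
        paste(sprintf("%.3f", x$overlap_ratios), collapse = ", "), "\n")
  }
  invisible(x)
}
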