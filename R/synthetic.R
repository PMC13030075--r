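#' Specify a synthetic RGB-D mushroom bed
#'
#' Defines a seeded scene: domed caps (spherical-cap elevation profiles,
#' `h(d) = apex * sqrt(1 - (d/R)^2)` for `d <= R`, giving a sharp depth edge
#' at the cap rim) sitting on a noisy compost plane, with optional per-cap
#' multiplicative growth per frame and harvest-removal frames. The same spec
#' and seed always render bit-identical frames, ground-truth label maps and
#' track ids.
#'
#' @param height,width Bed dimensions in pixels.
#' @param caps Data frame with columns `row`, `col` (apex center),
#'   `radius` (px), `apex` (elevation in depth units), and optionally
#'   `growth_rate` (fractional radius growth per frame, default 0) and
#'   `harvest_frame` (frame index from which the cap is absent; NA = never).
#' @param background_depth Compost plane depth from the camera (sensor
#'   units). Default 750.
#' @param depth_noise_sd Gaussian depth noise sigma (sensor units).
#'   Default 0.15.
#' @param compost_gray,cap_gray Mean intensities (0-255) of compost and cap
#'   pixels. Defaults 60 and 200.
#' @param speckle_sd Gaussian intensity noise sigma. Default 8.
#' @param seed Integer RNG seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height, width, caps,
                       background_depth = 750, depth_noise_sd = 0.15,
                       compost_gray = 60, cap_gray = 200, speckle_sd = 8,
                       seed = 1L) {
  caps <- tibble::as_tibble(caps)
  if (!"growth_rate" %in% names(caps)) caps$growth_rate <- 0
  if (!"harvest_frame" %in% names(caps)) caps$harvest_frame <- NA_integer_
  stopifnot(all(caps$radius > 0), all(caps$apex > 0))
  if (any(!is.na(caps$harvest_frame) & caps$harvest_frame < 1)) {
    stop_capseg("harvest_frame must be >= 1 (caps exist at frame 0)",
                "capseg_spec_error")
  }
  if (any(caps$row < 1 | caps$row > height | caps$col < 1 |
            caps$col > width)) {
    stop_capseg("cap center outside bed", "capseg_spec_error")
  }
  structure(list(height = height, width = width, caps = caps,
                 background_depth = background_depth,
                 depth_noise_sd = depth_noise_sd,
                 compost_gray = compost_gray, cap_gray = cap_gray,
                 speckle_sd = speckle_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render one synthetic frame with exact ground truth
#'
#' Depth is the compost plane minus the pointwise maximum of the cap
#' elevation fields (the higher surface wins where caps overlap, and
#' ground-truth ownership follows the higher cap), plus seeded Gaussian
#' noise. Color is the compost palette with cap pixels brightened, plus
#' seeded speckle. Harvested caps are absent from their harvest frame on;
#' ground-truth labels are the cap indices, stable across frames.
#'
#' @param spec A [scene_spec()].
#' @param frame_index Frame to render (0-based; growth and harvest apply).
#' @return List with `frame` ([rgbd_frame()]), `gt` (integer label map),
#'   `gt_ids` (cap indices present).
#' @export
render_frame <- function(spec, frame_index = 0L) {
  H <- spec$height; W <- spec$width
  best_h <- matrix(0, H, W)
  gt <- matrix(0L, H, W)
  present <- integer(0)
  for (i in seq_len(nrow(spec$caps))) {
    cp <- spec$caps[i, ]
    if (!is.na(cp$harvest_frame) && frame_index >= cp$harvest_frame) next
    present <- c(present, i)
    R <- cp$radius * (1 + cp$growth_rate)^frame_index
    r0 <- max(1L, floor(cp$row - R)); r1 <- min(H, ceiling(cp$row + R))
    c0 <- max(1L, floor(cp$col - R)); c1 <- min(W, ceiling(cp$col + R))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - cp$row)^2, (cols - cp$col)^2, `+`)
    inside <- d2 <= R^2
    h <- matrix(0, length(rows), length(cols))
    h[inside] <- cp$apex * sqrt(pmax(0, 1 - d2[inside] / R^2))
    sub_best <- best_h[rows, cols]
    sub_gt <- gt[rows, cols]
    # higher surface wins; rim pixels (h = 0) still belong to the cap; exact
    # height ties go to the earlier cap
    win <- inside & (h > sub_best | (h == sub_best & sub_gt == 0L))
    sub_best[win] <- h[win]
    best_h[rows, cols] <- sub_best
    sub_gt[win] <- i
    gt[rows, cols] <- sub_gt
  }
  seed_t <- (spec$seed * 1009L + frame_index * 97L) %% 2147483629L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed_t)
  depth <- spec$background_depth - best_h +
    matrix(stats::rnorm(H * W, sd = spec$depth_noise_sd), H, W)
  gray <- matrix(spec$compost_gray, H, W)
  gray[gt > 0L] <- spec$cap_gray
  gray <- gray + matrix(stats::rnorm(H * W, sd = spec$speckle_sd), H, W)
  gray <- pmin(pmax(round(gray), 0), 255)
  rgb <- array(rep(gray, 3L), c(H, W, 3L))
  list(frame = rgbd_frame(rgb, depth, frame_index = frame_index),
       gt = gt, gt_ids = present)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Render a time-lapse sequence
#'
#' @param spec A [scene_spec()].
#' @param n_frames Number of frames (0 .. n_frames-1).
#' @return List with `frames`, `gt_maps`, `gt_ids` (per frame).
#' @export
render_sequence <- function(spec, n_frames) {
  out <- lapply(seq_len(n_frames) - 1L, function(t) render_frame(spec, t))
  list(frames = lapply(out, `[[`, "frame"),
       gt_maps = lapply(out, `[[`, "gt"),
       gt_ids = lapply(out, `[[`, "gt_ids"))
}

#' Cut vertically overlapping strips from one rendered bed
#'
#' Emulates rail acquisition: frame 0 of the spec is rendered as one tall bed
#' and `n_frames` windows of height `frame_height` are cut at vertical steps
#' of `round((1 - overlap_ratio) * frame_height)`, so stitching can be tested
#' against the known composition. The bed must be at least
#' `frame_height + (n_frames - 1) * step` rows tall.
#'
#' @param spec A [scene_spec()] (its `height` is the bed height).
#' @param n_frames Number of strips.
#' @param overlap_ratio Fractional overlap between consecutive strips, in
#'   (0, 1).
#' @param frame_height Strip height in rows.
#' @return List with `strips` (list of [rgbd_frame()]), `bed`
#'   ([rgbd_frame()] of the full bed), `gt` (bed label map), `step`.
#' @export
render_overlapping_strips <- function(spec, n_frames, overlap_ratio,
                                      frame_height) {
  stopifnot(overlap_ratio > 0, overlap_ratio < 1)
  step <- round((1 - overlap_ratio) * frame_height)
  if (step < 1) stop_capseg("overlap_ratio too close to 1 for this height",
                            "capseg_spec_error")
  need <- frame_height + (n_frames - 1L) * step
  if (need > spec$height) {
    stop_capseg(sprintf(
      "bed height %d too short: need %d rows for %d strips",
      spec$height, need, n_frames), "capseg_spec_error")
  }
  rf <- render_frame(spec, 0L)
  bed <- rf$frame
  strips <- lapply(seq_len(n_frames), function(i) {
    top <- 1L + (i - 1L) * step
    rows <- top:(top + frame_height - 1L)
    rgbd_frame(bed$rgb[rows, , , drop = FALSE],
               bed$depth[rows, , drop = FALSE],
               bed$missing[rows, , drop = FALSE], i - 1L)
  })
  list(strips = strips, bed = bed, gt = rf$gt, step = step)
}
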