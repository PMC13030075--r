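#' Run the full segmentation + tracking pipeline on a frame sequence
#'
#' Orchestrates, per frame: preprocessing (Otsu foreground + background
#' homogenization), marker detection, radial-gradient boundary segmentation,
#' depth-guided watershed overlap resolution — then temporal association
#' across frames. Entirely deterministic for a fixed input and configuration.
#'
#' @param frames List of [rgbd_frame()]s (pre-stitched mosaics) or a single
#'   frame.
#' @param config A [pipeline_config()].
#' @return A list of class `capseg_run`: `elevations`, `markers` (per frame),
#'   `segmentations`, `resolved` (label maps), `tracks`
#'   ([track_sequence()] result), and `manifest` (per-stage instance counts).
#' @export
run_pipeline <- function(frames, config = pipeline_config()) {
  if (inherits(frames, "rgbd_frame")) frames <- list(frames)
  elevs <- vector("list", length(frames))
  marks <- vector("list", length(frames))
  segs <- vector("list", length(frames))
  resolved <- vector("list", length(frames))
  for (t in seq_along(frames)) {
    # a constant (empty-bed) image has no Otsu split: treat all background
    fg <- tryCatch(otsu_foreground(frames[[t]]$rgb),
                   capseg_degenerate_error = function(e) {
                     matrix(FALSE, nrow(frames[[t]]$depth),
                            ncol(frames[[t]]$depth))
                   })
    elevs[[t]] <- homogenize_background(frames[[t]]$depth, fg,
                                        frames[[t]]$missing)
    marks[[t]] <- detect_markers(elevs[[t]], config)
    segs[[t]] <- segment_frame(elevs[[t]], fg, marks[[t]], config)
    resolved[[t]] <- resolve_overlaps(segs[[t]], elevs[[t]], config)
  }
  tracks <- track_sequence(resolved, config)
  manifest <- purrr::map_dfr(seq_along(frames), function(t) {
    tibble::tibble(
      frame = t - 1L,
      n_markers = nrow(marks[[t]]),
      n_instances_raw = length(segs[[t]]$masks),
      n_instances_resolved = length(setdiff(unique(as.integer(resolved[[t]])),
                                            0L)),
      n_tracked = length(setdiff(unique(as.integer(tracks$maps[[t]])), 0L)))
  })
  structure(list(elevations = elevs, markers = marks, segmentations = segs,
                 resolved = resolved, tracks = tracks, manifest = manifest,
                 config = config),
            class = "capseg_run")
}

#' @export
print.capseg_run <- function(x, ...) {
  cat(sprintf("<capseg_run: %d frame(s)>\n", nrow(x$manifest)))
  print(x$manifest)
  invisible(x)
}
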