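#' Pipeline configuration
#'
#' A single validated object holding every tunable threshold in the pipeline.
#' Defaults reproduce the operating point of the depth-guided segmentation and
#' tracking method on 0.925 px/mm bed mosaics: a 100-px stitching template,
#' 5x5/stride-3 Gaussian peak response, an 18-px marker proximity filter,
#' 23x23 boundary patches with rings 1..11, the 10-neighbor / 10-px local
#' consistency pass and the 2.5-SD centroid pass, an IoU gate of 0.1 for
#' temporal association and 0.7 for detection scoring.
#'
#' @param template_height_px Height (rows) of the stitching template cut from
#'   the bottom of the previous frame. Default 100.
#' @param stitch_score_floor Minimum accepted normalized cross-correlation for
#'   a frame pair; below it stitching aborts. Default 0.5.
#' @param marker_window Side of the Gaussian-weighted sliding window used for
#'   the peak response (odd). Default 5.
#' @param marker_stride Stride of that window in pixels. Default 3.
#' @param marker_sigma Gaussian sigma (px) of the window weights. Default 1.1.
#' @param bilateral_d Bilateral filter neighborhood diameter (odd). Default 9.
#' @param bilateral_sigma_space Bilateral spatial sigma in response-grid cells.
#'   Default 5.
#' @param bilateral_sigma_range Bilateral range sigma in normalized elevation
#'   units. Default 0.1.
#' @param response_quantile High-elevation binarization quantile of the
#'   smoothed response. Default 0.80.
#' @param proximity_px Euclidean distance (px) under which weaker markers are
#'   suppressed. Default 18.
#' @param eval_merge_px Merge radius used only when scoring marker-level
#'   detection; `NULL` means "same as `proximity_px`".
#' @param patch_size Side of the per-marker elevation patch (odd); must equal
#'   `2 * max_ring + 1`. Default 23.
#' @param max_ring Outermost square ring index in the patch. Default 11.
#' @param n_rays Number of angular directions scanned per marker. Default 72.
#' @param neighbor_count Number of contour neighbors (total, half on each
#'   side) used by the local consistency pass. Default 10.
#' @param local_dev_px Maximum allowed deviation (px) of a point's radius from
#'   its local neighbor mean. Default 10.
#' @param global_sd_mult Centroid-distance outlier cut in standard deviations.
#'   Default 2.5.
#' @param seed_erode_iters Erosion iterations (3x3 box) applied to each
#'   instance's exclusively-owned region to form watershed seeds. Default 2.
#' @param speck_min_px Connected components smaller than this are removed in
#'   cleanup. Default 15.
#' @param ridge_sigma Gaussian sigma (px) applied before the Sobel ridge map.
#'   Default 1.
#' @param track_iou_tau Minimum IoU to accept a temporal match, in (0, 1).
#'   Default 0.1.
#' @param max_missed Consecutive unmatched frames after which an inactive
#'   track is terminated. Default 3.
#' @param rematch_inactive Should inactive (not yet terminated) tracks remain
#'   eligible for re-matching with their last observed mask? Default TRUE.
#' @param detect_iou IoU threshold defining a detection true positive.
#'   Default 0.7.
#' @param depth_scale Divisor mapping on-disk integer depth to sensor units.
#'   Default 1.
#' @param depth_sentinel On-disk depth value flagged as missing/invalid
#'   (`NA` to disable). Default 0.
#'
#' @return An object of class `capseg_config` (a validated named list).
#' @seealso [load_config()]
#' @export
pipeline_config <- function(template_height_px = 100,
                            stitch_score_floor = 0.5,
                            marker_window = 5,
                            marker_stride = 3,
                            marker_sigma = 1.1,
                            bilateral_d = 9,
                            bilateral_sigma_space = 5,
                            bilateral_sigma_range = 0.1,
                            response_quantile = 0.80,
                            proximity_px = 18,
                            eval_merge_px = NULL,
                            patch_size = 23,
                            max_ring = 11,
                            n_rays = 72,
                            neighbor_count = 10,
                            local_dev_px = 10,
                            global_sd_mult = 2.5,
                            seed_erode_iters = 2,
                            speck_min_px = 15,
                            ridge_sigma = 1,
                            track_iou_tau = 0.1,
                            max_missed = 3,
                            rematch_inactive = TRUE,
                            detect_iou = 0.7,
                            depth_scale = 1,
                            depth_sentinel = 0) {
  cfg <- as.list(environment())
  if (is.null(cfg$eval_merge_px)) cfg$eval_merge_px <- cfg$proximity_px
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_keys <- setdiff(names(cfg), c("rematch_inactive", "depth_sentinel"))
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_capseg(sprintf("config key '%s' must be a single finite number", k),
                  "capseg_config_error")
    }
  }
  pos_keys <- setdiff(num_keys, c("depth_sentinel"))
  for (k in pos_keys) {
    if (cfg[[k]] <= 0) {
      stop_capseg(sprintf("config key '%s' must be strictly positive", k),
                  "capseg_config_error")
    }
  }
  if (cfg$patch_size != 2 * cfg$max_ring + 1) {
    stop_capseg(sprintf(
      "config invariant violated: patch_size (%s) must equal 2*max_ring+1 (%s)",
      cfg$patch_size, 2 * cfg$max_ring + 1), "capseg_config_error")
  }
  if (cfg$track_iou_tau <= 0 || cfg$track_iou_tau >= 1) {
    stop_capseg("config key 'track_iou_tau' must lie in (0, 1)",
                "capseg_config_error")
  }
  if (cfg$marker_window %% 2 != 1) {
    stop_capseg("config key 'marker_window' must be odd", "capseg_config_error")
  }
  if (!is.logical(cfg$rematch_inactive) || length(cfg$rematch_inactive) != 1L) {
    stop_capseg("config key 'rematch_inactive' must be TRUE or FALSE",
                "capseg_config_error")
  }
  structure(cfg, class = "capseg_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Missing keys take the defaults of [pipeline_config()]; unknown keys are
#' rejected; the resulting object is validated (e.g. `patch_size` must equal
#' `2 * max_ring + 1`, `track_iou_tau` must lie in (0, 1)).
#'
#' @param path Path to a flat YAML key-value file, or `NULL` for all defaults.
#' @return A `capseg_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) {
    stop_capseg(sprintf("config file not found: %s", path), "capseg_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_capseg(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                "capseg_config_error")
  }
  do.call(pipeline_config, vals)
}

#' @export
print.capseg_config <- function(x, ...) {
  cat("<capseg pipeline configuration>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
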