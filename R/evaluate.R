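eval_report <- function(tp, fp, fn, level) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- tibble::tibble(level = level, tp = as.integer(tp),
                        fp = as.integer(fp), fn = as.integer(fn),
                        precision = precision, recall = recall, f1 = f1,
                        undefined = (tp + fp == 0) || (tp + fn == 0))
  structure(out, class = c("capseg_eval", class(out)))
}

#' Instance-level detection metrics
#'
#' Predicted and ground-truth instances are matched one-to-one by optimal
#' IoU assignment; matched pairs with IoU at or above `iou_thresh` are true
#' positives, remaining predictions false positives, remaining ground-truth
#' instances false negatives. Precision, recall and F1 follow the standard
#' definitions (zero-denominator cases report 0 and set the `undefined`
#' flag).
#'
#' @param pred,gt Integer instance label maps of equal shape (0 = background).
#' @param iou_thresh True-positive IoU threshold. Default 0.7.
#' @return A one-row `capseg_eval` tibble (tp, fp, fn, precision, recall, f1).
#' @export
detection_eval <- function(pred, gt, iou_thresh = 0.7) {
  stopifnot(all(dim(pred) == dim(gt)))
  pm <- label_map_to_masks(pred)
  gm <- label_map_to_masks(gt)
  if (!length(pm) || !length(gm)) {
    return(eval_report(0L, length(pm), length(gm), "detection-instance"))
  }
  acc <- assign_iou(iou_matrix(pm, gm), tau = 0)
  tp <- sum(acc$iou >= iou_thresh)
  eval_report(tp, length(pm) - tp, length(gm) - tp, "detection-instance")
}

#' Marker-level detection metrics
#'
#' A ground-truth instance counts as detected (one TP) when at least one
#' marker falls inside its region; multiple markers inside the same instance
#' are merged first and counted once. Markers falling inside no instance are
#' false positives (markers within `merge_px` of each other merge into one FP
#' cluster); instances containing no marker are false negatives.
#'
#' @param markers A `capseg_markers` tibble (columns row, col).
#' @param gt Integer ground-truth label map.
#' @param merge_px Merge radius for background marker clusters.
#' @return A one-row `capseg_eval` tibble.
#' @export
marker_detection_eval <- function(markers, gt, merge_px = 18) {
  gt_ids <- sort(setdiff(unique(as.integer(gt)), 0L))
  if (nrow(markers)) {
    owner <- gt[cbind(markers$row, markers$col)]
  } else {
    owner <- integer(0)
  }
  hit_ids <- unique(owner[owner > 0L])
  tp <- length(hit_ids)
  fn <- length(setdiff(gt_ids, hit_ids))
  bg <- markers[owner == 0L, , drop = FALSE]
  fp <- 0L
  if (nrow(bg)) {
    used <- logical(nrow(bg))
    for (i in seq_len(nrow(bg))) {
      if (used[i]) next
      fp <- fp + 1L
      d2 <- (bg$row - bg$row[i])^2 + (bg$col - bg$col[i])^2
      used[d2 <= merge_px^2] <- TRUE
    }
  }
  eval_report(tp, fp, fn, "detection-marker")
}

#' Pixel-level segmentation metrics
#'
#' Micro-averaged over pixels: for each matched prediction/ground-truth pair
#' (matching inherited from [detection_eval()]-style optimal IoU assignment),
#' TP are pixels labeled mushroom in both masks, FP pixels predicted but not
#' in the ground truth, FN ground-truth pixels missed. Unmatched predictions
#' contribute all their pixels as FP; unmatched ground-truth instances all
#' theirs as FN.
#'
#' @param pred,gt Integer instance label maps of equal shape.
#' @return A one-row `capseg_eval` tibble.
#' @export
segmentation_eval <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  pm <- label_map_to_masks(pred)
  gm <- label_map_to_masks(gt)
  tp <- fp <- fn <- 0L
  acc <- if (length(pm) && length(gm)) assign_iou(iou_matrix(pm, gm), tau = 0)
         else tibble::tibble(prev = integer(0), curr = integer(0),
                             iou = numeric(0))
  for (k in seq_len(nrow(acc))) {
    p <- pm[[acc$prev[k]]]; g <- gm[[acc$curr[k]]]
    tp <- tp + sum(p & g)
    fp <- fp + sum(p & !g)
    fn <- fn + sum(!p & g)
  }
  for (i in setdiff(seq_along(pm), acc$prev)) fp <- fp + sum(pm[[i]])
  for (j in setdiff(seq_along(gm), acc$curr)) fn <- fn + sum(gm[[j]])
  eval_report(tp, fp, fn, "segmentation-pixel")
}

#' Match predicted tracked instances to ground-truth instances per frame
#'
#' Helper producing the per-frame (ground-truth id, predicted global id)
#' correspondence that [tracking_consistency()] consumes, by optimal IoU
#' assignment with threshold `tau` per frame.
#'
#' @param pred_maps,gt_maps Lists of label maps, frame-aligned.
#' @param tau Minimum IoU for a frame-level correspondence. Default 0.5.
#' @return Tibble with columns `frame`, `gt_id`, `pred_id` (NA when the
#'   ground-truth instance found no partner that frame).
#' @export
match_tracks_to_gt <- function(pred_maps, gt_maps, tau = 0.5) {
  stopifnot(length(pred_maps) == length(gt_maps))
  purrr::map_dfr(seq_along(gt_maps), function(t) {
    gm <- label_map_to_masks(gt_maps[[t]])
    pm <- label_map_to_masks(pred_maps[[t]])
    gt_ids <- as.integer(names(gm))
    if (!length(gm)) return(NULL)
    pred_of <- rep(NA_integer_, length(gm))
    if (length(pm)) {
      acc <- assign_iou(iou_matrix(pm, gm), tau = tau)
      pred_of[acc$curr] <- as.integer(names(pm))[acc$prev]
    }
    tibble::tibble(frame = t - 1L, gt_id = gt_ids, pred_id = pred_of)
  })
}

#' Tracking consistency
#'
#' A ground-truth track is consistent when the same mushroom carries one
#' unchanged predicted id across every frame in which it appears — neither
#' identity swaps nor interruptions (frames with no matched prediction) are
#' tolerated. Returns the percentage of consistent tracks.
#'
#' @param assignments Tibble with columns `frame`, `gt_id`, `pred_id` (one row
#'   per ground-truth instance per frame it appears in; `pred_id` NA for a
#'   missed frame), e.g. from [match_tracks_to_gt()].
#' @return Percentage in \[0, 100\]; attribute `per_track` holds the per-track
#'   verdicts.
#' @export
tracking_consistency <- function(assignments) {
  if (!nrow(assignments)) {
    stop_capseg("no tracks to inspect: consistency undefined",
                "capseg_undefined_metric_error")
  }
  per <- assignments |>
    dplyr::group_by(.data$gt_id) |>
    dplyr::summarise(
      consistent = !anyNA(.data$pred_id) &&
        length(unique(.data$pred_id)) == 1L,
      .groups = "drop")
  pct <- 100 * mean(per$consistent)
  attr(pct, "per_track") <- per
  pct
}

#' @export
print.capseg_eval <- function(x, ...) {
  cat(sprintf(
    "<capseg_eval %s: TP %d FP %d FN %d | P %.3f R %.3f F1 %.3f%s>\n",
    x$level, x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
    if (x$undefined) " (zero-denominator flagged)" else ""))
  invisible(x)
}
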