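#' Intersection-over-union of two pixel masks
#'
#' `|A n B| / |A u B|`, defined as 0 when both masks are empty.
#'
#' @param mask_a,mask_b H x W logical matrices of equal shape.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  uni <- sum(mask_a | mask_b)
  if (uni == 0L) return(0)
  sum(mask_a & mask_b) / uni
}

# Pairwise IoU matrix between two lists of masks.
iou_matrix <- function(masks_a, masks_b) {
  m <- matrix(0, length(masks_a), length(masks_b))
  for (i in seq_along(masks_a)) {
    for (j in seq_along(masks_b)) m[i, j] <- mask_iou(masks_a[[i]],
                                                      masks_b[[j]])
  }
  m
}

#' Optimal one-to-one assignment maximizing total IoU
#'
#' Maximum-weight bipartite matching (Hungarian-equivalent optimum) over an
#' IoU matrix; only strictly positive IoU pairs are candidate edges, and
#' accepted matches additionally require `IoU >= tau`. Ties are broken toward
#' lower row/column indices (older ids) by a deterministic epsilon preference.
#'
#' @param iou Numeric matrix (rows = previous instances, cols = current).
#' @param tau Minimum IoU for an accepted match.
#' @return A tibble with columns `prev` (row index), `curr` (col index),
#'   `iou`, one row per accepted match.
#' @export
assign_iou <- function(iou, tau = 0.1) {
  empty <- tibble::tibble(prev = integer(0), curr = integer(0),
                          iou = numeric(0))
  if (!length(iou) || nrow(iou) == 0L || ncol(iou) == 0L) return(empty)
  edges <- which(iou > 0, arr.ind = TRUE)
  if (!nrow(edges)) return(empty)
  nr <- nrow(iou); nc <- ncol(iou)
  # deterministic tie-break: infinitesimal preference for older (lower) ids
  eps <- 1e-9 / (nr + nc + 1)
  w <- iou[edges] + eps * (2 * (nr + nc) - edges[, 1] - edges[, 2])
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(t(cbind(edges[, 1], nr + edges[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = w)
  match_of_row <- m$matching[seq_len(nr)]
  out <- purrr::map_dfr(seq_len(nr), function(i) {
    j <- match_of_row[i]
    if (is.na(j) || j <= nr) return(NULL)
    j <- j - nr
    tibble::tibble(prev = i, curr = as.integer(j), iou = iou[i, j])
  })
  if (!nrow(out)) return(empty)
  dplyr::filter(out, .data$iou >= tau)
}

#' Associate instances of the current frame with previous global ids
#'
#' Computes the pairwise IoU matrix between previous (globally labeled) and
#' current instances and accepts the optimal one-to-one assignment with
#' `IoU >= tau`. Matched current instances inherit the previous global id;
#' unmatched current instances get fresh ids; unmatched previous instances
#' are reported lost.
#'
#' @param prev Integer label map with global ids (or named list of masks).
#' @param curr Integer label map of the current frame (local ids).
#' @param tau IoU acceptance threshold (default 0.1).
#' @param next_id First id to hand to unmatched current instances; default one
#'   past the largest previous id.
#' @return List with `relabelled` (curr label map carrying global ids; NULL
#'   when `curr` was given as masks), `matches` (tibble prev_id, curr_id,
#'   global_id, iou), `new_ids`, `lost_ids`, `next_id`.
#' @export
associate <- function(prev, curr, tau = 0.1, next_id = NULL) {
  prev_masks <- if (is.list(prev)) prev else label_map_to_masks(prev)
  curr_is_map <- !is.list(curr)
  curr_masks <- if (curr_is_map) label_map_to_masks(curr) else curr
  prev_ids <- as.integer(names(prev_masks))
  curr_ids <- as.integer(names(curr_masks))
  if (is.null(next_id)) next_id <- if (length(prev_ids)) max(prev_ids) + 1L else 1L
  iou <- iou_matrix(prev_masks, curr_masks)
  acc <- assign_iou(iou, tau)
  matches <- tibble::tibble(prev_id = prev_ids[acc$prev],
                            curr_id = curr_ids[acc$curr],
                            global_id = prev_ids[acc$prev],
                            iou = acc$iou)
  unmatched_curr <- setdiff(seq_along(curr_masks), acc$curr)
  new_ids <- integer(0)
  assignment <- stats::setNames(matches$global_id, matches$curr_id)
  for (j in unmatched_curr) {
    assignment[as.character(curr_ids[j])] <- next_id
    new_ids <- c(new_ids, next_id)
    next_id <- next_id + 1L
  }
  lost_ids <- prev_ids[setdiff(seq_along(prev_masks), acc$prev)]
  relabelled <- NULL
  if (curr_is_map) {
    relabelled <- matrix(0L, nrow(curr), ncol(curr))
    for (j in seq_along(curr_masks)) {
      relabelled[curr_masks[[j]]] <- assignment[[as.character(curr_ids[j])]]
    }
    attr(relabelled, "provenance") <- "tracked"
  }
  list(relabelled = relabelled, matches = matches, new_ids = new_ids,
       lost_ids = lost_ids, next_id = next_id, assignment = assignment)
}

#' Track instances through a sequence of resolved label maps
#'
#' Frame 0 instances receive global ids 1..n. Each later frame is associated
#' with the set of live tracks (active tracks at their last observed mask;
#' inactive tracks too while inside the grace window, if `rematch_inactive`).
#' Matched tracks become active and reset their miss counter; unmatched live
#' tracks go inactive and are terminated once missed for more than
#' `max_missed` consecutive frames. Global ids are never reused.
#'
#' @param label_maps List of resolved integer label maps (equal shapes).
#' @param config A [pipeline_config()].
#' @return A list of class `capseg_tracks`: `maps` (tracked label maps),
#'   `table` (tibble: frame, global_id, area_px, centroid_row, centroid_col),
#'   `states` (tibble: global_id, state, first_seen, last_seen,
#'   frames_missed).
#' @export
track_sequence <- function(label_maps, config = pipeline_config()) {
  stopifnot(length(label_maps) >= 1L)
  tau <- config$track_iou_tau
  tracks <- list()   # id -> list(mask, state, last_seen, missed, first_seen)
  out_maps <- vector("list", length(label_maps))
  recs <- list()
  next_id <- 1L
  for (t in seq_along(label_maps)) {
    fr <- t - 1L  # 0-based frame index
    curr_masks <- label_map_to_masks(label_maps[[t]])
    live <- names(tracks)[vapply(tracks, function(tr)
      tr$state == "active" ||
        (config$rematch_inactive && tr$state == "inactive"), logical(1))]
    prev_masks <- lapply(tracks[live], `[[`, "mask")
    names(prev_masks) <- live
    a <- associate(prev_masks, curr_masks, tau, next_id)
    next_id <- a$next_id
    # write tracked map
    tm <- matrix(0L, nrow(label_maps[[t]]), ncol(label_maps[[t]]))
    for (nm in names(curr_masks)) {
      gid <- a$assignment[[nm]]
      tm[curr_masks[[nm]]] <- gid
      mask <- curr_masks[[nm]]
      if (is.null(tracks[[as.character(gid)]])) {
        tracks[[as.character(gid)]] <- list(mask = mask, state = "active",
                                            first_seen = fr, last_seen = fr,
                                            missed = 0L)
      } else {
        tr <- tracks[[as.character(gid)]]
        tr$mask <- mask; tr$state <- "active"; tr$last_seen <- fr
        tr$missed <- 0L
        tracks[[as.character(gid)]] <- tr
      }
      idx <- which(mask, arr.ind = TRUE)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        frame = fr, global_id = gid, area_px = nrow(idx),
        centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
    }
    matched_ids <- unname(a$assignment[names(curr_masks)])
    for (nm in setdiff(names(tracks), as.character(matched_ids))) {
      tr <- tracks[[nm]]
      if (tr$state == "terminated") next
      if (tr$last_seen < fr) {
        tr$missed <- tr$missed + 1L
        tr$state <- if (tr$missed > config$max_missed) "terminated"
                    else "inactive"
        tracks[[nm]] <- tr
      }
    }
    out_maps[[t]] <- structure(tm, provenance = "tracked")
  }
  table <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(frame = integer(0), global_id = integer(0),
                   area_px = integer(0), centroid_row = numeric(0),
                   centroid_col = numeric(0))
  states <- purrr::map_dfr(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    tibble::tibble(global_id = as.integer(nm), state = tr$state,
                   first_seen = tr$first_seen, last_seen = tr$last_seen,
                   frames_missed = tr$missed)
  })
  if (!nrow(states)) {
    states <- tibble::tibble(global_id = integer(0), state = character(0),
                             first_seen = integer(0), last_seen = integer(0),
                             frames_missed = integer(0))
  }
  states <- dplyr::arrange(states, .data$global_id)
  structure(list(maps = out_maps, table = table, states = states),
            class = "capseg_tracks")
}

#' @export
print.capseg_tracks <- function(x, ...) {
  cat(sprintf("<capseg_tracks: %d frame(s), %d global id(s)>\n",
              length(x$maps), nrow(x$states)))
  invisible(x)
}
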