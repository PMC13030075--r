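#' Tidy a metric report
#'
#' Long tibble with one row per metric, broom-style.
#' @param x A `capseg_eval` one-row report.
#' @param ... Unused.
#' @return Tibble with columns `level`, `metric`, `value`.
#' @export
tidy.capseg_eval <- function(x, ...) {
  tibble::tibble(level = x$level,
                 metric = c("tp", "fp", "fn", "precision", "recall", "f1"),
                 value = c(x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
}

#' Glance at a metric report
#' @param x A `capseg_eval` report.
#' @param ... Unused.
#' @return The one-row tibble itself (already glance-shaped).
#' @export
glance.capseg_eval <- function(x, ...) tibble::as_tibble(x)

#' Tidy a tracking result
#'
#' @param x A `capseg_tracks` object.
#' @param ... Unused.
#' @return The per-frame track table (frame, global_id, area_px, centroids).
#' @export
tidy.capseg_tracks <- function(x, ...) x$table

#' Glance at a tracking result
#' @param x A `capseg_tracks` object.
#' @param ... Unused.
#' @return One-row tibble: frames, total tracks, active/terminated counts.
#' @export
glance.capseg_tracks <- function(x, ...) {
  tibble::tibble(n_frames = length(x$maps),
                 n_tracks = nrow(x$states),
                 n_active = sum(x$states$state == "active"),
                 n_inactive = sum(x$states$state == "inactive"),
                 n_terminated = sum(x$states$state == "terminated"))
}

#' Turn an object into a tidy tibble
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an object
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")
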