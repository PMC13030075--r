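mat_to_df <- function(m, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value_name]] <- as.vector(m)
  tibble::as_tibble(df)
}

#' Plot an elevation map
#'
#' Raster heatmap of normalized elevation (row 1 at the top, matching image
#' coordinates), optionally overlaying detected markers as crosses.
#'
#' @param elev An `elevation_map`.
#' @param markers Optional `capseg_markers` tibble.
#' @return A ggplot object.
#' @export
plot_elevation <- function(elev, markers = NULL) {
  df <- mat_to_df(elev$values, "elevation")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$elevation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "elevation") +
    ggplot2::theme_minimal()
  if (!is.null(markers) && nrow(markers)) {
    p <- p + ggplot2::geom_point(
      data = markers, ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, shape = 4, colour = "red", size = 2, stroke = 1)
  }
  p
}

#' Plot an instance label map
#'
#' @param labels Integer label map (0 = background).
#' @param show_ids Label each instance with its id at the centroid?
#' @return A ggplot object.
#' @export
plot_label_map <- function(labels, show_ids = TRUE) {
  df <- mat_to_df(labels, "id")
  df$id <- factor(ifelse(df$id == 0L, NA, df$id))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$id)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_discrete(na.value = "grey15") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "instance") +
    ggplot2::theme_minimal()
  if (show_ids) {
    cent <- df |>
      dplyr::filter(!is.na(.data$id)) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                       .groups = "drop")
    if (nrow(cent)) {
      p <- p + ggplot2::geom_text(
        data = cent, ggplot2::aes(x = .data$col, y = .data$row,
                                  label = .data$id),
        inherit.aes = FALSE, colour = "white", size = 3)
    }
  }
  p
}

#' Plot per-track area trajectories
#'
#' @param tracks A `capseg_tracks` object (or its `table`).
#' @return A ggplot object (area in px against frame, one line per global id).
#' @export
plot_tracks <- function(tracks) {
  tab <- if (inherits(tracks, "capseg_tracks")) tracks$table else tracks
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$frame, y = .data$area_px,
                                    colour = factor(.data$global_id))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "mask area (px)", colour = "track id") +
    ggplot2::theme_minimal()
}

#' @rdname plot_elevation
#' @param object,... autoplot interface.
#' @method autoplot elevation_map
#' @export
autoplot.elevation_map <- function(object, ...) plot_elevation(object, ...)

#' @rdname plot_tracks
#' @param object,... autoplot interface.
#' @method autoplot capseg_tracks
#' @export
autoplot.capseg_tracks <- function(object, ...) plot_tracks(object)
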