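#' Construct an RGB-D frame
#'
#' The atomic input: one pixel-aligned color image and depth map of identical
#' resolution. Depth is in sensor units with larger = farther from the camera;
#' invalid pixels are carried in an explicit `missing` mask, never as silent
#' zeros.
#'
#' @param rgb H x W x 3 numeric array, intensities 0-255.
#' @param depth H x W numeric matrix (sensor units).
#' @param missing Optional H x W logical matrix flagging invalid depth.
#' @param frame_index Integer >= 0 identifying the frame in a sequence.
#' @return An object of class `rgbd_frame`.
#' @export
rgbd_frame <- function(rgb, depth, missing = NULL, frame_index = 0L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop_capseg("rgb must be an H x W x 3 array", "capseg_dimension_error")
  }
  if (!is.matrix(depth)) stop_capseg("depth must be a matrix",
                                     "capseg_dimension_error")
  if (!all(dim(rgb)[1:2] == dim(depth))) {
    stop_capseg(sprintf(
      "rgb (%d x %d) and depth (%d x %d) dimensions differ",
      dim(rgb)[1], dim(rgb)[2], nrow(depth), ncol(depth)),
      "capseg_dimension_error")
  }
  if (nrow(depth) < 1L || ncol(depth) < 1L) {
    stop_capseg("frame must have H, W >= 1", "capseg_dimension_error")
  }
  if (is.null(missing)) missing <- matrix(FALSE, nrow(depth), ncol(depth))
  stopifnot(is.logical(missing), all(dim(missing) == dim(depth)))
  structure(list(rgb = rgb, depth = depth, missing = missing,
                 frame_index = as.integer(frame_index)),
            class = "rgbd_frame")
}

#' @export
print.rgbd_frame <- function(x, ...) {
  cat(sprintf("<rgbd_frame %d x %d, frame_index %d, %d missing depth px>\n",
              nrow(x$depth), ncol(x$depth), x$frame_index, sum(x$missing)))
  invisible(x)
}

read_raster_gray <- function(path) {
  if (!file.exists(path)) {
    stop_capseg(sprintf("cannot read raster: %s", path), "capseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop_capseg(sprintf("unsupported raster format '%s' (%s)", ext, path),
                "capseg_io_error"))
  if (ext == "csv") return(unname(img))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Read a registered RGB-D frame pair from disk
#'
#' The color file is an 8-bit PNG/TIFF; depth is a 16-bit PNG/TIFF raster
#' (decoded values scaled back by 65535 then divided by `depth_scale`) or a
#' plain CSV matrix holding sensor units directly. Pixels equal to the
#' configured sentinel are flagged missing.
#'
#' @param color_path Path to the color image.
#' @param depth_path Path to the depth raster or CSV matrix.
#' @param config A [pipeline_config()] (supplies `depth_scale`,
#'   `depth_sentinel`).
#' @param frame_index Frame index stored on the result.
#' @return An [rgbd_frame()].
#' @export
read_frame <- function(color_path, depth_path, config = pipeline_config(),
                       frame_index = 0L) {
  if (!file.exists(color_path)) {
    stop_capseg(sprintf("cannot read color image: %s", color_path),
                "capseg_io_error")
  }
  ext <- tolower(tools::file_ext(color_path))
  col <- switch(ext,
    png = png::readPNG(color_path),
    tif = ,
    tiff = tiff::readTIFF(color_path),
    stop_capseg(sprintf("unsupported color format '%s' (%s)", ext, color_path),
                "capseg_io_error"))
  if (length(dim(col)) == 2L) col <- array(rep(col, 3L), c(dim(col), 3L))
  if (dim(col)[3] > 3L) col <- col[, , 1:3, drop = FALSE]
  rgb <- round(col * 255)

  dext <- tolower(tools::file_ext(depth_path))
  dep <- read_raster_gray(depth_path)
  if (dext %in% c("png", "tif", "tiff")) dep <- round(dep * 65535)
  if (!all(dim(rgb)[1:2] == dim(dep))) {
    stop_capseg(sprintf(
      "color (%d x %d) and depth (%d x %d) shapes differ",
      dim(rgb)[1], dim(rgb)[2], nrow(dep), ncol(dep)),
      "capseg_dimension_error")
  }
  miss <- matrix(FALSE, nrow(dep), ncol(dep))
  if (!is.null(config$depth_sentinel) && !is.na(config$depth_sentinel)) {
    miss <- dep == config$depth_sentinel
  }
  rgbd_frame(rgb, dep / config$depth_scale, miss, frame_index)
}

#' Write an instance label map losslessly
#'
#' 16-bit TIFF (extension `.tif`/`.tiff`) or plain CSV. Round-trips exactly for
#' label values up to 65535; larger labels with the 16-bit backend raise an
#' overflow error.
#'
#' @param labels Integer matrix, 0 = background.
#' @param path Output path; the extension selects the backend.
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0)) {
    stop_capseg("label maps must be non-negative", "capseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff", "png")) {
    if (max(labels) > 65535) {
      stop_capseg(sprintf(
        "label %d exceeds 16-bit storage capacity (65535)", max(labels)),
        "capseg_overflow_error")
    }
    if (ext == "png") {
      # PNG writing is 8-bit-safe only in this backend; keep labels <= 255.
      if (max(labels) > 255) {
        stop_capseg("PNG label backend is 8-bit; use .tif for labels > 255",
                    "capseg_overflow_error")
      }
      png::writePNG(labels / 255, path)
    } else {
      tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
    }
  } else if (ext == "csv") {
    utils::write.table(labels, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop_capseg(sprintf("unsupported label format '%s'", ext),
                "capseg_io_error")
  }
  invisible(path)
}

#' Read an instance label map written by [write_label_map()]
#' @param path Input path.
#' @return Integer matrix, 0 = background.
#' @export
read_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- read_raster_gray(path)
  if (ext %in% c("tif", "tiff")) m <- round(m * 65535)
  if (ext == "png") m <- round(m * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a depth matrix
#'
#' 16-bit TIFF (values multiplied by `depth_scale` and clamped to 0..65535) or
#' CSV (exact).
#' @param depth Numeric matrix in sensor units.
#' @param path Output path (`.tif`/`.tiff`/`.csv`).
#' @param config Supplies `depth_scale`.
#' @export
write_depth <- function(depth, path, config = pipeline_config()) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    v <- round(depth * config$depth_scale)
    if (any(v < 0 | v > 65535)) {
      stop_capseg("scaled depth out of 16-bit range", "capseg_overflow_error")
    }
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  } else if (ext == "csv") {
    utils::write.table(depth, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    stop_capseg(sprintf("unsupported depth format '%s'", ext),
                "capseg_io_error")
  }
  invisible(path)
}

#' Write a color image (8-bit PNG)
#' @param rgb H x W x 3 array, 0-255.
#' @param path Output `.png` path.
#' @export
write_color <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}
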