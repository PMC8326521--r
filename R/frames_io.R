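#' Read a frame sequence from a directory of numbered images
#'
#' Frames are numbered PNG (or TIFF) images in a directory; they are sorted
#' by the numeric part of the file name so `frame_2.png` precedes
#' `frame_10.png`. All frames must share the same dimensions and are decoded
#' to RGB arrays with values in \[0, 1\] (8-bit source precision).
#'
#' @param path Directory containing the frames, or a character vector of
#'   image file paths already in temporal order.
#' @param frame_rate Frames per second; metadata only (default 30).
#' @param pattern Regular expression selecting frame files when `path` is a
#'   directory (default matches .png/.tif/.tiff).
#' @return A `frame_sequence`: list with `frames` (list of height x width x 3
#'   arrays), `frame_rate`, and `dim` (height, width).
#' @export
read_frames <- function(path, frame_rate = 30,
                        pattern = "\\.(png|tif|tiff)$") {
  stopifnot(frame_rate > 0)
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no frame images found in ", path)
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    files <- files[order(num, basename(files))]
  } else {
    files <- path
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("frame file not found: ", missing[1])
  }
  frames <- lapply(files, read_image)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (ncol(dims) > 1 && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("frames have mixed dimensions: expected ",
         dims[1, 1], "x", dims[2, 1])
  structure(list(frames = frames, frame_rate = frame_rate,
                 dim = dims[, 1]),
            class = "frame_sequence")
}

#' Read a single image as an RGB array
#'
#' @param path PNG or TIFF file.
#' @return height x width x 3 numeric array, values in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  as_rgb_array(img)
}

as_rgb_array <- function(img) {
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Write a frame sequence as numbered PNG files
#'
#' @param fs A `frame_sequence` or plain list of RGB arrays.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix (default "frame").
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(fs, dir, prefix = "frame") {
  frames <- if (inherits(fs, "frame_sequence")) fs$frames else fs
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  width <- max(4L, nchar(length(frames)))
  paths <- file.path(dir, sprintf("%s_%0*d.png", prefix, width,
                                  seq_along(frames) - 1L))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames, %dx%d px, %.4g fps\n",
              length(x$frames), x$dim[2], x$dim[1], x$frame_rate))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Pixel-to-micrometre scale calibration
#'
#' The conversion factor delta (micrometres per pixel) is measured from a
#' marker of known physical length embedded in the imaging chip:
#' delta = marker length in um / marker length in px. The chip carries 1 mm
#' and 0.1 mm markers for this purpose.
#'
#' @param marker_px Measured marker length in pixels (> 0).
#' @param marker_um Physical marker length in micrometres (> 0,
#'   default 1000).
#' @return A `scale_calibration`: list with `delta` (um/px), `marker_px`,
#'   `marker_um`.
#' @examples
#' calibrate_scale(460, 1000)  # delta ~ 2.174 um/px
#' @export
calibrate_scale <- function(marker_px, marker_um = 1000) {
  if (!is.numeric(marker_px) || length(marker_px) != 1L || marker_px <= 0)
    stop("marker_px must be a single positive number")
  if (!is.numeric(marker_um) || length(marker_um) != 1L || marker_um <= 0)
    stop("marker_um must be a single positive number")
  structure(list(delta = marker_um / marker_px,
                 marker_px = marker_px, marker_um = marker_um),
            class = "scale_calibration")
}

#' Build a scale calibration directly from delta
#'
#' @param delta Micrometres per pixel (> 0).
#' @return A `scale_calibration`.
#' @export
scale_from_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a single positive number")
  structure(list(delta = delta, marker_px = NA_real_, marker_um = NA_real_),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("scale_calibration: delta = %.6g um/px\n", x$delta))
  invisible(x)
}
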