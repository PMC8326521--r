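#' Convert an RGB frame to a grayscale intensity matrix
#'
#' Luminance-weighted conversion (0.299 R + 0.587 G + 0.114 B) onto an
#' 8-bit-style 0-255 intensity scale, which is the scale all thresholds and
#' biases in this package are expressed on.
#'
#' @param frame height x width x 3 array with values in \[0, 1\].
#' @return height x width numeric matrix, values in \[0, 255\].
#' @export
to_gray <- function(frame) {
  if (length(dim(frame)) == 2L) return(frame * 255)
  255 * (0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
}

#' Background subtraction with low-pass smoothing
#'
#' Both the frame and the (islet-free) background image are converted to
#' grayscale, smoothed with a Gaussian low-pass filter, and subtracted; the
#' result is the per-pixel absolute difference, so islets darker or brighter
#' than the channel both appear as positive foreground signal.
#'
#' @param frame,background RGB arrays of identical dimensions.
#' @param smoothing_radius Gaussian sigma in pixels (0 disables smoothing;
#'   default 2).
#' @return height x width foreground intensity matrix (0-255 scale).
#' @export
subtract_background <- function(frame, background, smoothing_radius = 2) {
  if (!identical(dim(frame)[1:2], dim(background)[1:2]))
    stop("frame and background dimensions differ")
  f <- to_gray(frame)
  b <- to_gray(background)
  if (smoothing_radius > 0) {
    f <- EBImage::gblur(f, sigma = smoothing_radius)
    b <- EBImage::gblur(b, sigma = smoothing_radius)
  }
  abs(f - b)
}

#' Foreground thresholding by biased Otsu
#'
#' The threshold is Otsu's inter-class-variance-maximising level on a
#' 256-bin histogram of the foreground image, shifted by a signed `bias`
#' (0-255 intensity units). Pixels strictly above the shifted threshold are
#' foreground. A constant image yields an all-background mask.
#'
#' @param foreground Single-channel intensity matrix (0-255 scale).
#' @param bias Signed threshold offset in intensity units (default 0).
#' @return Logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(foreground, bias = 0) {
  if (length(dim(foreground)) != 2L)
    stop("foreground must be single-channel")
  rng <- range(foreground)
  if (diff(rng) == 0) return(foreground > Inf)
  th <- EBImage::otsu(EBImage::Image(foreground / 255),
                      range = c(0, 1), levels = 256) * 255
  foreground > (th + bias)
}

#' Split touching islets with a distance-transform-seeded watershed
#'
#' The binary mask is distance-transformed (Euclidean distance to the
#' nearest background pixel); pixels whose distance exceeds
#' `dt_threshold_frac` times the maximum distance of their connected
#' component become seed candidates, so only the central core of each blob
#' survives. Morphological opening with a disc then deletes small seed
#' fragments (debris rather than islets). Finally a seeded watershed on the
#' inverted distance transform, restricted to the original mask, assigns
#' every foreground pixel to the nearest seed, one label per seed.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param dt_threshold_frac Seed threshold as a fraction of each component's
#'   distance maximum, in (0, 1) (default 0.4). Larger values carve deeper
#'   between touching islets: splitting two equal discs whose centres are
#'   `s` radii apart needs a fraction above `sqrt(1 - (s/2)^2)`.
#' @param opening_radius Disc radius in pixels for the opening step
#'   (default 2; 0 disables).
#' @return Integer label matrix: 0 = background, 1..n = regions.
#' @export
split_touching <- function(mask, dt_threshold_frac = 0.4,
                           opening_radius = 2) {
  mask <- mask > 0
  storage.mode(mask) <- "integer"
  if (!any(mask > 0))
    return(matrix(0L, nrow(mask), ncol(mask)))
  if (dt_threshold_frac <= 0 || dt_threshold_frac >= 1)
    stop("dt_threshold_frac must be in (0, 1)")
  d <- EBImage::distmap(mask)
  comp <- EBImage::bwlabel(mask)
  fg <- comp > 0
  labs <- comp[fg]
  cm <- vapply(split(as.numeric(d)[fg], labs), max, numeric(1))
  cm_vec <- numeric(max(labs))
  cm_vec[as.integer(names(cm))] <- cm
  thr <- matrix(0, nrow(mask), ncol(mask))
  thr[fg] <- dt_threshold_frac * cm_vec[labs]
  seeds <- (d > thr & fg) * 1
  if (opening_radius > 0)
    seeds <- EBImage::opening(
      seeds, EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc"))
  seeds <- EBImage::bwlabel(seeds)
  if (max(seeds) == 0)
    return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::propagate(EBImage::Image(-d / max(d)), seeds = seeds,
                            mask = mask > 0, lambda = 1e-4)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  lab
}

#' Measure per-region detections
#'
#' For each labelled region: pixel area, centroid, outer boundary contour,
#' corrected chain-code perimeter, convex hull area, least-squares fitted
#' ellipse semi-axes, count of
#' DTZ-positive pixels (hue inside `hue_range` on the 0-360 degree scale),
#' and whether the region touches the raster border. Regions smaller than
#' `min_area` pixels, or whose ellipse fit fails, are flagged degenerate and
#' excluded by downstream stages.
#'
#' @param labeled Integer label matrix (0 = background).
#' @param frame RGB array of the same height/width.
#' @param hue_range Length-2 vector of hue limits in degrees (default
#'   c(310, 360), the red window of dithizone staining).
#' @param frame_index 0-based frame index recorded in each detection.
#' @param min_area Minimum region area in pixels (default 5, the minimum
#'   for a determined ellipse fit).
#' @return A data.frame with one row per region: `label`, `frame_index`,
#'   `centroid_x`, `centroid_y` (0-based pixel coordinates, x = column),
#'   `area_px`, `perimeter_px`, `hull_area_px`, `ellipse_major_px`,
#'   `ellipse_minor_px` (semi-axes), `dtz_positive_px`, `touches_edge`,
#'   `degenerate`, and a `contour` list column of n x 2 (x, y) matrices.
#' @export
measure_regions <- function(labeled, frame, hue_range = c(310, 360),
                            frame_index = 0L, min_area = 5L) {
  if (!identical(dim(labeled), dim(frame)[1:2]))
    stop("labeled mask and frame dimensions differ")
  n <- max(labeled)
  if (n == 0) return(empty_detections())
  h <- nrow(labeled); w <- ncol(labeled)
  idx <- which(labeled > 0)
  labs <- labeled[idx]
  by_lab <- split(idx, labs)
  contours <- EBImage::ocontour(labeled)
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  hue <- rep(NA_real_, length(idx))
  hsv <- grDevices::rgb2hsv(r = r[idx], g = g[idx], b = b[idx],
                            maxColorValue = 1)
  hue <- hsv[1, ] * 360
  hue_by_lab <- split(hue, labs)
  rows <- lapply(seq_len(n), function(k) {
    px <- by_lab[[as.character(k)]]
    if (is.null(px)) return(NULL)
    area <- length(px)
    rr <- (px - 1L) %% h + 1L      # row (1-based)
    cc <- (px - 1L) %/% h + 1L     # col (1-based)
    oc <- contours[[k]]            # 0-based (row, col) chain
    cx <- mean(cc) - 1; cy <- mean(rr) - 1
    contour <- cbind(x = oc[, 2], y = oc[, 1])
    perim <- chain_perimeter(contour)
    # The hull polygon through boundary pixel centres never exceeds the
    # pixel count for digitally convex regions (Pick's theorem: it misses
    # the half-pixel rim), while the pixel count never exceeds the true
    # hull; the max of the two preserves hull_area >= area_px with
    # near-zero bias for convex regions.
    hull <- max(convex_hull_area(contour[, 1], contour[, 2]), area)
    fit <- if (area >= min_area) fit_ellipse(contour[, 1], contour[, 2])
           else NULL
    hk <- hue_by_lab[[as.character(k)]]
    dtz <- sum(!is.na(hk) & hk >= hue_range[1] & hk <= hue_range[2])
    data.frame(
      label = k, frame_index = frame_index,
      centroid_x = cx, centroid_y = cy,
      area_px = area, perimeter_px = perim, hull_area_px = hull,
      ellipse_major_px = if (is.null(fit)) NA_real_ else fit$semiaxes[1],
      ellipse_minor_px = if (is.null(fit)) NA_real_ else fit$semiaxes[2],
      dtz_positive_px = dtz,
      touches_edge = any(rr == 1L | rr == h | cc == 1L | cc == w),
      degenerate = area < min_area || is.null(fit)
    )
  })
  out <- do.call(rbind, rows)
  out$contour <- lapply(seq_len(n), function(k)
    cbind(x = contours[[k]][, 2], y = contours[[k]][, 1]))
  out
}

empty_detections <- function() {
  out <- data.frame(
    label = integer(), frame_index = integer(),
    centroid_x = numeric(), centroid_y = numeric(),
    area_px = numeric(), perimeter_px = numeric(),
    hull_area_px = numeric(),
    ellipse_major_px = numeric(), ellipse_minor_px = numeric(),
    dtz_positive_px = numeric(),
    touches_edge = logical(), degenerate = logical()
  )
  out$contour <- list()
  out
}

#' Segment one frame end to end
#'
#' Convenience wrapper chaining [subtract_background()], [binarize()],
#' [split_touching()] and [measure_regions()].
#'
#' @inheritParams subtract_background
#' @inheritParams binarize
#' @inheritParams split_touching
#' @inheritParams measure_regions
#' @return Detections data.frame (see [measure_regions()]).
#' @export
segment_frame <- function(frame, background, smoothing_radius = 2,
                          bias = 0, dt_threshold_frac = 0.4,
                          opening_radius = 2, hue_range = c(310, 360),
                          frame_index = 0L, min_area = 5L) {
  fg <- subtract_background(frame, background, smoothing_radius)
  mask <- binarize(fg, bias)
  lab <- split_touching(mask, dt_threshold_frac, opening_radius)
  measure_regions(lab, frame, hue_range, frame_index, min_area)
}
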