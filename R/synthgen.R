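#' Configuration for a synthetic flow-channel scene
#'
#' Describes a scene of elliptical islets translating along +x (the channel
#' axis) over a static background, as seen by the imaging window. Islets
#' are laid out in horizontal lanes and staggered in x so that no two
#' overlap in any frame (validation mode); each islet carries a stained
#' angular sector covering a known fraction of its area, rendered in the
#' dithizone-red hue, with the remainder in an unstained yellow-brown hue.
#'
#' Defaults emulate gentle syringe-pump loading: a mean advance of 15 px
#' per frame along the channel with ~1 px frame-to-frame jitter, lateral
#' drift of ~1 px SD, equivalent radii of 12-40 px (islet-scale objects at
#' ~2.2 um/px), axis ratios up to 1.5, and mild sensor noise (SD 2 on the
#' 0-255 scale).
#'
#' @param n_islets Number of islets crossing the field of view.
#' @param radius_range Equivalent-radius range in px (semi-axes are
#'   `r*sqrt(q)` and `r/sqrt(q)` for axis ratio q, preserving area).
#' @param axis_ratio_range Major/minor axis ratio range (>= 1).
#' @param velocity Mean advance along +x in px/frame.
#' @param velocity_jitter_sd SD of per-frame x-advance jitter (px).
#' @param y_jitter_sd SD of per-frame lateral drift (px).
#' @param stain_fraction_range Range of per-islet stained area fractions.
#' @param stained_hue,unstained_hue Hues in degrees (defaults 330 and 55:
#'   inside and outside the 310-360 degree DTZ window).
#' @param saturation HSV saturation of islet pixels.
#' @param stained_value,unstained_value HSV value of the stained and
#'   unstained tissue. The defaults (0.55 and 0.31) give both tissues the
#'   same luminance contrast against the default background, so intensity
#'   thresholding clips stained and unstained rims symmetrically and the
#'   rendered stain fraction is recovered without luminance bias.
#' @param background_level Flat background gray level (0-255).
#' @param background_gradient Peak-to-peak amplitude of an optional smooth
#'   horizontal gradient added to the background (0 disables).
#' @param noise_sd Additive Gaussian noise SD (0-255 scale).
#' @param frame_size c(height, width) in px.
#' @param n_frames Number of frames; `NULL` (default) runs until the last
#'   islet has fully exited.
#' @param seed RNG seed; a fixed seed gives byte-identical scenes.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(n_islets = 50,
                         radius_range = c(12, 40),
                         axis_ratio_range = c(1, 1.5),
                         velocity = 15,
                         velocity_jitter_sd = 1,
                         y_jitter_sd = 1,
                         stain_fraction_range = c(0.4, 1),
                         stained_hue = 330,
                         unstained_hue = 55,
                         saturation = 0.8,
                         stained_value = 0.55,
                         unstained_value = 0.31,
                         background_level = 200,
                         background_gradient = 0,
                         noise_sd = 2,
                         frame_size = c(480, 640),
                         n_frames = NULL,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_islets >= 0, all(radius_range > 0),
            axis_ratio_range[1] >= 1, velocity > 0,
            all(stain_fraction_range >= 0 & stain_fraction_range <= 1),
            stained_hue >= 0, stained_hue <= 360,
            unstained_hue >= 0, unstained_hue <= 360,
            noise_sd >= 0, length(frame_size) == 2)
  structure(cfg, class = "scene_config")
}

hue_to_rgb <- function(hue, s, v) {
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue / 360, s, v))) / 255
}

#' Render a synthetic scene with ground truth
#'
#' Samples per-islet geometry (semi-axes, orientation, lane, stagger,
#' stain sector) from `config`, renders every frame plus the islet-free
#' background frame, and records exact ground truth: per (frame, islet)
#' the centre, semi-axes, orientation, rendered pixel area and rendered
#' stained-pixel count (both counted before noise is added).
#'
#' Islets are placed in lanes tall enough for the largest semi-axis plus
#' jitter margin; within a lane, consecutive islets are staggered so their
#' bounding discs never overlap (validated per frame; violation is an
#' error suggesting fewer or smaller islets).
#'
#' @param config A [scene_config()].
#' @return List with `frames` (a `frame_sequence`), `background` (RGB
#'   array), `truth` (data.frame, one row per visible (frame, islet)),
#'   `islets` (per-islet static parameters) and `config`.
#' @export
make_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  h <- config$frame_size[1]; w <- config$frame_size[2]
  n <- config$n_islets

  # background: flat gray plus optional smooth horizontal gradient
  bg_row <- rep(config$background_level / 255, w)
  if (config$background_gradient > 0)
    bg_row <- bg_row + config$background_gradient / 255 *
      (sin(seq(0, pi, length.out = w)) - 0.5)
  bg_mat <- matrix(bg_row, h, w, byrow = TRUE)
  background <- array(rep(bg_mat, 3), dim = c(h, w, 3))

  if (n == 0) {
    n_frames <- config$n_frames %||% 10L
    frames <- lapply(seq_len(n_frames), function(i)
      add_noise(background, config$noise_sd))
    return(list(
      frames = structure(list(frames = frames,
                              frame_rate = 30, dim = c(h, w)),
                         class = "frame_sequence"),
      background = background,
      truth = empty_truth(), islets = data.frame(), config = config))
  }

  r <- stats::runif(n, config$radius_range[1], config$radius_range[2])
  q <- stats::runif(n, config$axis_ratio_range[1], config$axis_ratio_range[2])
  a <- r * sqrt(q); b <- r / sqrt(q)
  theta <- stats::runif(n, 0, pi)
  f_stain <- stats::runif(n, config$stain_fraction_range[1],
                          config$stain_fraction_range[2])
  t0 <- stats::runif(n, 0, 2 * pi)

  margin <- 6  # jitter + rasterisation margin, px
  lane_h <- 2 * max(a) + 2 * margin
  n_lanes <- max(1L, floor(h / lane_h))
  lane_y <- (seq_len(n_lanes) - 0.5) * (h / n_lanes)
  lane <- rep(seq_len(n_lanes), length.out = n)

  # stagger islets within each lane so bounding discs never meet
  start_x <- numeric(n)
  for (ln in seq_len(n_lanes)) {
    ids <- which(lane == ln)
    if (length(ids) == 0) next
    gap <- 3 * config$velocity + 2 * margin
    edge <- -max(a[ids]) - margin
    for (i in ids) {
      start_x[i] <- edge - a[i]
      edge <- start_x[i] - a[i] - gap
    }
  }
  y0 <- lane_y[lane]

  transit <- (w + 2 * max(a) + abs(min(start_x))) / config$velocity
  n_frames <- config$n_frames %||% as.integer(ceiling(transit) + 3)

  # Jittered trajectories. The x-advance jitter is common-mode (pump
  # pulsation advances all islets together), so staggered islets keep
  # their spacing; lateral jitter is independent per islet around its
  # lane centre (no random walk across lanes).
  dx <- config$velocity +
    stats::rnorm(n_frames, 0, config$velocity_jitter_sd)
  x_adv <- cumsum(dx) - dx[1]
  xs <- outer(x_adv, rep(1, n)) + outer(rep(1, n_frames), start_x)
  ys <- outer(rep(1, n_frames), y0) +
    matrix(stats::rnorm(n_frames * n, 0, config$y_jitter_sd), n_frames, n)
  ys <- pmin(pmax(ys, max(a) + 2), h - max(a) - 3)

  col_stained <- hue_to_rgb(config$stained_hue, config$saturation,
                            config$stained_value)
  col_unstained <- hue_to_rgb(config$unstained_hue, config$saturation,
                              config$unstained_value)

  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    img <- background
    rows <- list()
    vis <- which(xs[fi, ] > -(a + 2) & xs[fi, ] < w + a + 2)
    # non-overlap validation on bounding discs
    if (length(vis) > 1) {
      cx <- xs[fi, vis]; cy <- ys[fi, vis]
      dd <- as.matrix(stats::dist(cbind(cx, cy)))
      lim <- outer(a[vis], a[vis], "+") + 1
      diag(dd) <- Inf
      if (any(dd < lim))
        stop("islets overlap in frame ", fi - 1,
             "; use fewer or smaller islets")
    }
    for (i in vis) {
      ren <- render_ellipse(img, xs[fi, i], ys[fi, i], a[i], b[i],
                            theta[i], f_stain[i], t0[i],
                            col_stained, col_unstained)
      img <- ren$img
      if (ren$area > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          frame_index = fi - 1L, islet_id = i,
          x = xs[fi, i], y = ys[fi, i],
          semi_major = a[i], semi_minor = b[i], angle = theta[i],
          stain_fraction = f_stain[i],
          area_px = ren$area, stained_px = ren$stained,
          touches_edge = ren$touches_edge)
    }
    truth[[fi]] <- if (length(rows)) do.call(rbind, rows) else NULL
    frames[[fi]] <- add_noise(img, config$noise_sd)
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) truth <- empty_truth()

  list(
    frames = structure(list(frames = frames, frame_rate = 30,
                            dim = c(h, w)),
                       class = "frame_sequence"),
    background = background,
    truth = truth,
    islets = data.frame(islet_id = seq_len(n), semi_major = a,
                        semi_minor = b, equiv_radius = r, angle = theta,
                        stain_fraction = f_stain, lane = lane,
                        start_x = start_x),
    config = config
  )
}

empty_truth <- function() {
  data.frame(frame_index = integer(), islet_id = integer(),
             x = numeric(), y = numeric(), semi_major = numeric(),
             semi_minor = numeric(), angle = numeric(),
             stain_fraction = numeric(), area_px = integer(),
             stained_px = integer(), touches_edge = logical())
}

# Rasterise one rotated ellipse with a stained parametric-angle sector.
# A sector of parametric angle 2*pi*f covers exactly the fraction f of the
# ellipse area (the area element is (1/2) a b dt), so the rendered stained
# pixel fraction matches f up to rasterisation error.
render_ellipse <- function(img, cx, cy, a, b, theta, f_stain, t0,
                           col_stained, col_unstained) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ext <- ceiling(max(a, b)) + 1
  c1 <- max(1L, floor(cx - ext) + 1L); c2 <- min(w, ceiling(cx + ext) + 1L)
  r1 <- max(1L, floor(cy - ext) + 1L); r2 <- min(h, ceiling(cy + ext) + 1L)
  if (c1 > c2 || r1 > r2)
    return(list(img = img, area = 0L, stained = 0L, touches_edge = FALSE))
  cols <- c1:c2; rows <- r1:r2
  px <- outer(rep(1, length(rows)), cols - 1) - cx   # 0-based x
  py <- outer(rows - 1, rep(1, length(cols))) - cy   # 0-based y
  u <- px * cos(theta) + py * sin(theta)
  v <- -px * sin(theta) + py * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside))
    return(list(img = img, area = 0L, stained = 0L, touches_edge = FALSE))
  t <- (atan2(v / b, u / a) - t0) %% (2 * pi)
  stained <- inside & t < 2 * pi * f_stain
  unstained <- inside & !stained
  ri <- row(inside); ci <- col(inside)
  for (ch in 1:3) {
    img[cbind(ri[stained] + r1 - 1L, ci[stained] + c1 - 1L, ch)] <-
      col_stained[ch]
    img[cbind(ri[unstained] + r1 - 1L, ci[unstained] + c1 - 1L, ch)] <-
      col_unstained[ch]
  }
  ridx <- ri[inside] + r1 - 1L
  cidx <- ci[inside] + c1 - 1L
  list(img = img, area = sum(inside), stained = sum(stained),
       touches_edge = any(ridx == 1L | ridx == h | cidx == 1L | cidx == w) ||
         cx - a < 0 || cx + a > w - 1)
}

add_noise <- function(img, noise_sd) {
  if (noise_sd <= 0) return(img)
  out <- img + stats::rnorm(length(img), 0, noise_sd / 255)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Write a scene to disk as a plain-file fixture
#'
#' Writes `frames/frame_%04d.png`, `background.png` and
#' `ground_truth.csv` (one row per visible (frame, islet)) plus
#' `islets.csv` (static per-islet parameters) under `dir`.
#'
#' @param scene Output of [make_scene()].
#' @param dir Target directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames(scene$frames, file.path(dir, "frames"))
  png::writePNG(scene$background, file.path(dir, "background.png"))
  utils::write.csv(scene$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$islets, file.path(dir, "islets.csv"),
                   row.names = FALSE)
  invisible(dir)
}
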