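#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline reads, with its default.
#' See [validate_config()] for the validation rules.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = NULL,
    background = NULL,
    frame_rate = 30,
    scale = list(delta_um_per_px = NULL, marker_px = NULL,
                 marker_um = 1000),
    segmentation = list(smoothing_radius = 2, otsu_bias = 0,
                        dt_threshold_frac = 0.4, opening_radius = 2,
                        min_area = 5),
    purity = list(hue_min_deg = 310, hue_max_deg = 360),
    tracking = list(w_x = 1.0, w_y = 0.5, w_area = 1.0, j_max = 2.0,
                    max_missed = 2, min_track_length = 2,
                    solver = "greedy"),
    metrics = list(volume_variant = "major", diameter_binwidth = 25,
                   ratio_binwidth = 0.1),
    output = list(debug_images = FALSE, verbosity = 1)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key ", full, " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Applies defaults, rejects unknown keys, and range-checks every value
#' (hues in \[0, 360\], fractions in (0, 1), weights >= 0, and so on)
#' before any frame is processed. The scale may be given either directly
#' as `scale.delta_um_per_px` or as the `scale.marker_px` /
#' `scale.marker_um` pair measured from the chip's embedded marker.
#'
#' @param config Partial configuration: a nested list or the path of a
#'   YAML file.
#' @return Full configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) return(config)
  cfg <- merge_config(default_config(), config)
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("config: ", msg)
  chk(cfg$frame_rate > 0, "frame_rate must be > 0")
  s <- cfg$segmentation
  chk(s$smoothing_radius >= 0, "segmentation.smoothing_radius must be >= 0")
  chk(s$dt_threshold_frac > 0 && s$dt_threshold_frac < 1,
      "segmentation.dt_threshold_frac must be in (0, 1)")
  chk(s$opening_radius >= 0, "segmentation.opening_radius must be >= 0")
  chk(s$min_area >= 1, "segmentation.min_area must be >= 1")
  p <- cfg$purity
  chk(p$hue_min_deg >= 0 && p$hue_max_deg <= 360 &&
        p$hue_min_deg < p$hue_max_deg,
      "purity hue range must satisfy 0 <= hue_min_deg < hue_max_deg <= 360")
  tr <- cfg$tracking
  chk(all(c(tr$w_x, tr$w_y, tr$w_area) >= 0),
      "tracking weights must be >= 0")
  chk(tr$j_max > 0, "tracking.j_max must be > 0")
  chk(tr$max_missed >= 0, "tracking.max_missed must be >= 0")
  chk(tr$min_track_length >= 1, "tracking.min_track_length must be >= 1")
  chk(tr$solver %in% c("greedy", "optimal"),
      "tracking.solver must be 'greedy' or 'optimal'")
  chk(cfg$metrics$volume_variant %in% c("major", "minor"),
      "metrics.volume_variant must be 'major' or 'minor'")
  if (!is.null(cfg$scale$delta_um_per_px))
    chk(cfg$scale$delta_um_per_px > 0, "scale.delta_um_per_px must be > 0")
  if (!is.null(cfg$scale$marker_px))
    chk(cfg$scale$marker_px > 0 && cfg$scale$marker_um > 0,
        "scale marker lengths must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

config_scale <- function(cfg) {
  if (!is.null(cfg$scale$delta_um_per_px))
    scale_from_delta(cfg$scale$delta_um_per_px)
  else if (!is.null(cfg$scale$marker_px))
    calibrate_scale(cfg$scale$marker_px, cfg$scale$marker_um)
  else stop("config: scale.delta_um_per_px or scale.marker_px required")
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in order -- object detection (foreground
#' extraction), cell segmentation, cell tracking, feature extraction and
#' report generation -- and, when `out_dir` is given, writes `islets.csv`,
#' `tracks.csv`, `report.json`, a `config.yaml` echo of the effective
#' configuration, and optional per-frame labelled-mask PNGs under
#' `debug/`. Identical configuration and inputs give identical outputs.
#'
#' @param config A [validate_config()] result, partial list, or YAML path.
#'   Instead of paths, `frames` / `background` may be passed in memory.
#' @param frames Optional in-memory `frame_sequence` (overrides
#'   `config$input`).
#' @param background Optional in-memory RGB background array (overrides
#'   `config$background`).
#' @param out_dir Optional output directory.
#' @return List with `report` (a `sample_report`), `records`, `tracks`,
#'   `detections` and `config`.
#' @export
run_pipeline <- function(config = list(), frames = NULL,
                         background = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  log_stage <- function(stage, t0) {
    if (cfg$output$verbosity > 0)
      message(sprintf("[isletflow] %-18s %6.2f s", stage,
                      as.numeric(Sys.time()) - t0))
  }
  scale <- config_scale(cfg)

  t0 <- as.numeric(Sys.time())
  if (is.null(frames)) {
    if (is.null(cfg$input)) stop("config: input is required")
    frames <- read_frames(cfg$input, cfg$frame_rate)
  }
  if (is.null(background)) {
    if (is.null(cfg$background)) stop("config: background is required")
    background <- read_image(cfg$background)
  }
  if (!all(dim(background)[1:2] == frames$dim))
    stop("background dimensions do not match the frames")
  s <- cfg$segmentation
  # the background is static, so smooth it once
  bg_gray <- to_gray(background)
  if (s$smoothing_radius > 0)
    bg_gray <- EBImage::gblur(bg_gray, sigma = s$smoothing_radius)
  masks <- lapply(frames$frames, function(f) {
    fg <- to_gray(f)
    if (s$smoothing_radius > 0)
      fg <- EBImage::gblur(fg, sigma = s$smoothing_radius)
    binarize(abs(fg - bg_gray), s$otsu_bias)
  })
  log_stage("object detection", t0)

  t0 <- as.numeric(Sys.time())
  hue_range <- c(cfg$purity$hue_min_deg, cfg$purity$hue_max_deg)
  detections <- lapply(seq_along(masks), function(i) {
    lab <- split_touching(masks[[i]], s$dt_threshold_frac,
                          s$opening_radius)
    measure_regions(lab, frames$frames[[i]], hue_range,
                    frame_index = i - 1L, min_area = s$min_area)
  })
  if (!is.null(out_dir) && cfg$output$debug_images)
    write_debug_masks(detections, frames, out_dir)
  log_stage("cell segmentation", t0)

  t0 <- as.numeric(Sys.time())
  tr <- cfg$tracking
  tracks <- track_detections(
    detections, cost_weights(tr$w_x, tr$w_y, tr$w_area),
    j_max = tr$j_max, max_missed = tr$max_missed, solver = tr$solver)
  final <- finalize_tracks(tracks, tr$min_track_length)
  log_stage("cell tracking", t0)

  t0 <- as.numeric(Sys.time())
  records <- islet_records(final, scale)
  log_stage("feature extraction", t0)

  t0 <- as.numeric(Sys.time())
  report <- summarize_sample(records, cfg$metrics$volume_variant,
                             cfg$metrics$diameter_binwidth,
                             cfg$metrics$ratio_binwidth)
  if (report$islet_count == 0)
    warning("no islets detected; report has count 0")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "islets.csv"),
                     row.names = FALSE)
    utils::write.csv(tracks_table(final), file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  }
  log_stage("report generation", t0)

  list(report = report, records = records, tracks = final,
       detections = detections, config = cfg)
}

# Per-frame labelled-mask debug PNGs (label -> colour lookup).
write_debug_masks <- function(detections, frames, out_dir) {
  dbg <- file.path(out_dir, "debug")
  dir.create(dbg, recursive = TRUE, showWarnings = FALSE)
  h <- frames$dim[1]; w <- frames$dim[2]
  pal <- t(grDevices::col2rgb(grDevices::rainbow(12))) / 255
  for (i in seq_along(detections)) {
    det <- detections[[i]]
    img <- array(0, dim = c(h, w, 3))
    for (k in seq_len(nrow(det))) {
      ct <- det$contour[[k]]
      colr <- pal[(det$label[k] - 1L) %% nrow(pal) + 1L, ]
      idx <- cbind(ct[, 2] + 1L, ct[, 1] + 1L)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- colr[ch]
        img[, , ch] <- plane
      }
    }
    png::writePNG(img, file.path(dbg, sprintf("mask_%04d.png", i - 1L)))
  }
}
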