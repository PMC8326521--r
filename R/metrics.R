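#' Volume of a 150 um diameter sphere, in cubic micrometres
#'
#' The reference volume of one islet equivalent (IEq): a sphere of radius
#' 75 um, (4/3) pi 75^3 ~ 1.767e6 um^3.
#'
#' @return Scalar volume in um^3.
#' @export
v150_um3 <- function() 4 / 3 * pi * 75^3

#' The standard IEq conversion table
#'
#' Islets are classified into eight 50-um diameter classes
#' (50-100, 101-150, ..., 351-400, >400 um) and each islet contributes its
#' class multiplier to the sample IEq total. For real-valued diameters the
#' printed integer ranges are read with round-to-nearest semantics, so the
#' class boundaries fall at 100.5, 150.5, ... um; diameters below 50 um are
#' fragments and contribute 0.
#'
#' @return List with `lower` (lower diameter edges, um), `labels`, and
#'   `multipliers`.
#' @export
ieq_table <- function() {
  list(
    lower = c(50, 100.5, 150.5, 200.5, 250.5, 300.5, 350.5, 400.5),
    labels = c("50-100", "101-150", "151-200", "201-250",
               "251-300", "301-350", "351-400", ">400"),
    multipliers = c(0.167, 0.667, 1.685, 3.499, 6.315, 10.352,
                    15.833, 22.750)
  )
}

#' Equivalent spherical diameter of a region
#'
#' Diameter of the circle with the same area as the measured region,
#' converted to micrometres: `D = 2 sqrt(area_px / pi) * delta`.
#'
#' @param area_px Region area in pixels (> 0).
#' @param scale A `scale_calibration` (or delta in um/px).
#' @return Diameter in micrometres.
#' @export
equivalent_diameter <- function(area_px, scale) {
  delta <- if (inherits(scale, "scale_calibration")) scale$delta else scale
  if (any(area_px <= 0)) stop("area_px must be > 0")
  2 * sqrt(area_px / pi) * delta
}

#' Assign IEq classes and total islet equivalents
#'
#' @param diameters_um Vector of islet diameters in micrometres (> 0).
#' @param table IEq table (default [ieq_table()]).
#' @return List with `bin` (integer class 1-8, NA for fragments < 50 um),
#'   `label` (class label or "fragment"), `contribution` (per-islet
#'   multiplier, 0 for fragments) and `total_ieq`.
#' @export
assign_ieq <- function(diameters_um, table = ieq_table()) {
  if (any(diameters_um <= 0)) stop("diameters must be > 0")
  bin <- findInterval(diameters_um, table$lower)
  bin[bin == 0] <- NA_integer_
  contribution <- ifelse(is.na(bin), 0, table$multipliers[bin])
  list(bin = bin,
       label = ifelse(is.na(bin), "fragment", table$labels[bin]),
       contribution = contribution,
       total_ieq = sum(contribution))
}

#' Ellipsoid volume from fitted 2-D ellipse semi-axes
#'
#' The fitted 2-D ellipse is revolved into an ellipsoid whose third axis
#' repeats either the major semi-axis (`variant = "major"`,
#' V = 4/3 pi Ma^2 Mi) or the minor semi-axis (`variant = "minor"`,
#' V = 4/3 pi Ma Mi^2). For a circle (Ma = Mi = r) both give the sphere
#' volume 4/3 pi r^3.
#'
#' @param major,minor Semi-axis lengths, same length unit, `major >= minor
#'   > 0`.
#' @param variant `"major"` or `"minor"`.
#' @return Volume in the cube of the input unit.
#' @export
ellipsoid_volume <- function(major, minor, variant = c("major", "minor")) {
  variant <- match.arg(variant)
  if (any(minor <= 0) || any(major < minor))
    stop("require major >= minor > 0")
  if (variant == "major") 4 / 3 * pi * major^2 * minor
  else 4 / 3 * pi * major * minor^2
}

#' Frame-averaged islet volume of a track, in cubic micrometres
#'
#' Per qualifying frame (non-degenerate, not touching the image border) the
#' ellipsoid volume is computed from the fitted semi-axes in pixels; the
#' frame average is converted to um^3 with delta^3.
#'
#' @param track A track object from [track_detections()].
#' @param scale A `scale_calibration` (or delta in um/px).
#' @param variant `"major"` or `"minor"` (see [ellipsoid_volume()]).
#' @return Volume in um^3, or NA when no detection qualifies.
#' @export
track_volume <- function(track, scale, variant = "major") {
  delta <- if (inherits(scale, "scale_calibration")) scale$delta else scale
  d <- track$detections
  d <- d[!d$degenerate & !d$touches_edge, , drop = FALSE]
  if (nrow(d) == 0) return(NA_real_)
  v_px <- ellipsoid_volume(d$ellipse_major_px, d$ellipse_minor_px, variant)
  mean(v_px) * delta^3
}

#' Sample volume implied by an IEq total
#'
#' `IEqV = IEq x V150`, the volume of `total_ieq` ideal 150-um islets.
#'
#' @param total_ieq Total islet equivalents (>= 0).
#' @return Volume in um^3.
#' @export
ieq_volume <- function(total_ieq) {
  if (any(total_ieq < 0)) stop("total_ieq must be >= 0")
  total_ieq * v150_um3()
}

#' Circularity of a region
#'
#' `C = area / (perimeter^2 / (4 pi))`, i.e. the ratio of the region's area
#' to the area of the circle with the same perimeter; 1 for a perfect
#' circle, lower for elongated or irregular shapes. Discretisation can push
#' the raw ratio slightly above 1 for rasterised convex shapes, so the
#' result is clamped to \[0, 1\].
#'
#' @param area Region area (> 0); any unit, consistent with `perimeter`.
#' @param perimeter Region perimeter (> 0).
#' @param clamp Clamp to \[0, 1\] (default TRUE).
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter, clamp = TRUE) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be > 0")
  c_raw <- area / (perimeter^2 / (4 * pi))
  if (clamp) pmin(pmax(c_raw, 0), 1) else c_raw
}

#' Solidity of a region
#'
#' Ratio of the region's area to the area of its convex hull; 1 for convex
#' regions, lower the more fragmented or concave the region is. Clamped to
#' \[0, 1\] to absorb rasterisation slack.
#'
#' @param area Region area (> 0).
#' @param hull_area Convex hull area (> 0), same unit.
#' @param tol Allowed relative discretisation excess of `area` over
#'   `hull_area` (default 0.05) before an error is raised.
#' @return Dimensionless solidity.
#' @export
solidity <- function(area, hull_area, tol = 0.05) {
  if (any(area <= 0) || any(hull_area <= 0))
    stop("area and hull_area must be > 0")
  if (any(hull_area < area * (1 - tol)))
    stop("hull_area smaller than region area beyond discretisation slack")
  pmin(pmax(area / hull_area, 0), 1)
}

#' DTZ-positive area ratio
#'
#' Fraction of an islet's area whose pixels are dithizone-stained (red
#' hue); estimates the true (beta-cell containing) islet tissue fraction of
#' the tracked object, i.e. its purity. Trapped islets embedded in
#' unstained acinar tissue score below 1.
#'
#' @param dtz_positive_px Stained pixel count (0 <= dtz <= area).
#' @param area_px Region pixel count (> 0).
#' @return Ratio in \[0, 1\].
#' @export
dtz_ratio <- function(dtz_positive_px, area_px) {
  if (any(area_px <= 0)) stop("area_px must be > 0")
  if (any(dtz_positive_px < 0 | dtz_positive_px > area_px))
    stop("dtz_positive_px must lie in [0, area_px]")
  dtz_positive_px / area_px
}

#' Convert finalised tracks to per-islet records in physical units
#'
#' Scalar metrics (diameter, circularity, solidity, DTZ ratio) are averaged
#' over each track's qualifying frames (non-degenerate, away from the image
#' border), mirroring the frame-averaging of volume; both ellipsoid volume
#' variants are reported.
#'
#' @param tracks Finalised tracks (see [finalize_tracks()]).
#' @param scale A `scale_calibration` (or delta in um/px).
#' @param table IEq table (default [ieq_table()]).
#' @return data.frame with one row per islet: `track_id`, `n_frames`,
#'   `diameter_um`, `volume_major_um3`, `volume_minor_um3`, `circularity`,
#'   `solidity`, `dtz_ratio`, `ieq_label`, `ieq_contribution`.
#' @export
islet_records <- function(tracks, scale, table = ieq_table()) {
  delta <- if (inherits(scale, "scale_calibration")) scale$delta else scale
  rows <- lapply(tracks, function(tr) {
    d <- tr$detections
    d <- d[!d$degenerate & !d$touches_edge, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    data.frame(
      track_id = tr$track_id,
      n_frames = nrow(d),
      diameter_um = mean(equivalent_diameter(d$area_px, delta)),
      volume_major_um3 = mean(ellipsoid_volume(
        d$ellipse_major_px, d$ellipse_minor_px, "major")) * delta^3,
      volume_minor_um3 = mean(ellipsoid_volume(
        d$ellipse_major_px, d$ellipse_minor_px, "minor")) * delta^3,
      circularity = mean(circularity(d$area_px, d$perimeter_px)),
      solidity = mean(solidity(d$area_px, d$hull_area_px)),
      dtz_ratio = mean(dtz_ratio(d$dtz_positive_px, d$area_px)),
      dtz_positive_px = sum(d$dtz_positive_px),
      area_px = sum(d$area_px)
    )
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) {
    rec <- data.frame(track_id = integer(), n_frames = integer(),
                      diameter_um = numeric(), volume_major_um3 = numeric(),
                      volume_minor_um3 = numeric(), circularity = numeric(),
                      solidity = numeric(), dtz_ratio = numeric(),
                      dtz_positive_px = numeric(), area_px = numeric(),
                      ieq_label = character(),
                      ieq_contribution = numeric())
    return(rec)
  }
  ieq <- assign_ieq(rec$diameter_um, table)
  rec$ieq_label <- ieq$label
  rec$ieq_contribution <- ieq$contribution
  rec
}

#' Sample-level mass report
#'
#' Aggregates per-islet records into the sample report: islet count, total
#' IEq and the volume it implies (IEqV), total ellipsoid-fitting volumes
#' (both variants), per-metric mean and SD (n-1 denominator), histograms,
#' and the sample DTZ ratio both as the mean of per-islet ratios and as the
#' area-weighted aggregate (total stained area / total islet area).
#'
#' @param records data.frame from [islet_records()].
#' @param volume_variant Which ellipsoid variant fills the headline
#'   `total_efv_um3` (default `"major"`).
#' @param diameter_binwidth,ratio_binwidth Histogram bin widths for
#'   diameter (um, default 25) and for the dimensionless ratio metrics
#'   (default 0.1).
#' @return List of class `sample_report`.
#' @export
summarize_sample <- function(records, volume_variant = "major",
                             diameter_binwidth = 25,
                             ratio_binwidth = 0.1) {
  n <- nrow(records)
  msd <- function(x) if (n == 0) list(mean = NA_real_, sd = NA_real_)
    else list(mean = mean(x), sd = stats::sd(x))
  hist_of <- function(x, bw) {
    if (n == 0) return(list(breaks = numeric(), counts = integer()))
    breaks <- seq(0, (max(x) %/% bw + 1) * bw, by = bw)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  }
  total_ieq <- if (n == 0) 0 else sum(records$ieq_contribution)
  vol_col <- paste0("volume_", volume_variant, "_um3")
  structure(list(
    islet_count = n,
    total_ieq = total_ieq,
    ieqv_um3 = ieq_volume(total_ieq),
    v150_um3 = v150_um3(),
    total_efv_um3 = if (n == 0) 0 else sum(records[[vol_col]]),
    total_efv_major_um3 = if (n == 0) 0 else sum(records$volume_major_um3),
    total_efv_minor_um3 = if (n == 0) 0 else sum(records$volume_minor_um3),
    volume_variant = volume_variant,
    diameter_um = msd(records$diameter_um),
    circularity = msd(records$circularity),
    solidity = msd(records$solidity),
    dtz_ratio = msd(records$dtz_ratio),
    sample_dtz_ratio = if (n == 0) NA_real_
      else sum(records$dtz_positive_px) / sum(records$area_px),
    histograms = list(
      diameter_um = hist_of(records$diameter_um, diameter_binwidth),
      circularity = hist_of(records$circularity, ratio_binwidth),
      solidity = hist_of(records$solidity, ratio_binwidth),
      dtz_ratio = hist_of(records$dtz_ratio, ratio_binwidth)
    )
  ), class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("Islet sample report\n")
  cat(sprintf("  islets counted : %d\n", x$islet_count))
  cat(sprintf("  total IEq      : %.3f (IEqV %.4g um^3)\n",
              x$total_ieq, x$ieqv_um3))
  cat(sprintf("  total EFV      : %.4g um^3 (%s-axis variant)\n",
              x$total_efv_um3, x$volume_variant))
  if (x$islet_count > 0) {
    fmt <- function(nm, v, unit = "")
      cat(sprintf("  %-15s: %.3f +/- %.3f%s\n", nm, v$mean, v$sd, unit))
    fmt("diameter", x$diameter_um, " um")
    fmt("circularity", x$circularity)
    fmt("solidity", x$solidity)
    fmt("DTZ+ ratio", x$dtz_ratio)
    cat(sprintf("  sample DTZ+    : %.3f (area-weighted)\n",
                x$sample_dtz_ratio))
  }
  invisible(x)
}
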