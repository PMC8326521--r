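# Independent oracles and small raster fixtures used across test files.

# Rasterise a rotated ellipse: matrix of 0/1, centre (cx, cy) in 0-based
# pixel coordinates, semi-axes a >= b, orientation theta.
raster_ellipse <- function(h, w, cx, cy, a, b = a, theta = 0) {
  x <- outer(rep(1, h), 0:(w - 1)) - cx
  y <- outer(0:(h - 1), rep(1, w)) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) * 1
}

raster_disk <- function(h, w, cx, cy, r) raster_ellipse(h, w, cx, cy, r, r)

# Paint a flat-colour RGB frame from a binary mask.
mask_to_rgb <- function(mask, fg_rgb, bg_rgb = c(0.8, 0.8, 0.8)) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- ifelse(mask > 0, fg_rgb[ch], bg_rgb[ch])
  img
}

hue_rgb <- function(hue_deg, s = 0.8, v = 0.55)
  as.numeric(grDevices::col2rgb(grDevices::hsv(hue_deg / 360, s, v))) / 255

# Brute-force Otsu: maximise between-class variance over all 256 levels.
otsu_brute <- function(x) {
  counts <- tabulate(pmin(pmax(floor(x), 0), 255) + 1, nbins = 256)
  p <- counts / sum(counts)
  lev <- 0:255
  best <- -Inf; best_t <- 0
  for (t in 0:254) {
    w0 <- sum(p[lev <= t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lev[lev <= t] * p[lev <= t]) / w0
    m1 <- sum(lev[lev > t] * p[lev > t]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# Exhaustive convex hull area: a point is a hull vertex candidate set;
# test every ordered pair as a supporting edge (O(n^3)).
hull_area_brute <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  on_hull <- logical(n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
    if (all(cr <= 1e-9)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  cx <- mean(hx); cy <- mean(hy)
  ord <- order(atan2(hy - cy, hx - cx))
  shoelace_brute(hx[ord], hy[ord])
}

# Independent shoelace: accumulate cross products one vertex at a time.
shoelace_brute <- function(x, y) {
  n <- length(x); s <- 0
  for (i in 1:n) {
    j <- if (i == n) 1 else i + 1
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# Brute-force minimum-cost assignment (with non-assignment allowed at
# cost j_max each, forbidden pairs = Inf): enumerate all injective maps.
assign_brute <- function(J, j_max) {
  nt <- nrow(J); nd <- ncol(J)
  best <- list(cost = Inf, assignment = rep(NA_integer_, nt))
  options <- c(NA_integer_, seq_len(nd))
  grid <- do.call(expand.grid, rep(list(options), nt))
  for (k in seq_len(nrow(grid))) {
    asg <- as.integer(grid[k, ])
    used <- asg[!is.na(asg)]
    if (anyDuplicated(used)) next
    cost <- 0
    ok <- TRUE
    for (i in seq_len(nt)) {
      if (is.na(asg[i])) cost <- cost + j_max
      else if (!is.finite(J[i, asg[i]]) || J[i, asg[i]] > j_max) {
        ok <- FALSE; break
      } else cost <- cost + J[i, asg[i]]
    }
    if (!ok) next
    cost <- cost + (nd - length(used)) * j_max
    if (cost < best$cost - 1e-12) best <- list(cost = cost, assignment = asg)
  }
  best
}

# Detection rows synthesised directly (bypassing rendering) for tracking
# tests: one row per (frame, islet) from exact positions.
truth_detections <- function(frame_index, x, y, area,
                             touches_edge = FALSE) {
  n <- length(x)
  out <- data.frame(
    label = seq_len(n), frame_index = frame_index,
    centroid_x = x, centroid_y = y,
    area_px = area, perimeter_px = 2 * sqrt(pi * area),
    hull_area_px = area * 1.01,
    ellipse_major_px = sqrt(area / pi),
    ellipse_minor_px = sqrt(area / pi),
    dtz_positive_px = area,
    touches_edge = rep_len(touches_edge, n),
    degenerate = FALSE)
  out$contour <- rep(list(cbind(x = 0, y = 0)), n)
  out
}
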