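test_that("subtracting a frame from itself gives zero foreground", {
  img <- array(runif(40 * 50 * 3), dim = c(40, 50, 3))
  fg <- subtract_background(img, img, smoothing_radius = 2)
  expect_true(all(fg == 0))
  expect_error(
    subtract_background(img, array(0, dim = c(30, 50, 3))),
    "dimensions differ")
})

test_that("foreground is localised to the object added over the background", {
  bg <- array(0.8, dim = c(80, 100, 3))
  disk <- raster_disk(80, 100, 50, 40, 12)
  frame <- mask_to_rgb(disk, c(0.2, 0.2, 0.2))
  fg <- subtract_background(frame, bg, smoothing_radius = 1)
  far <- raster_disk(80, 100, 50, 40, 20) == 0   # outside a wide margin
  expect_lt(max(fg[far]), 1)
  expect_gt(max(fg[disk > 0]), 100)
})

test_that("sensor noise stays almost entirely below the chosen threshold", {
  set.seed(21)
  bg <- array(0.7, dim = c(100, 120, 3))
  noisy <- bg + array(rnorm(length(bg), 0, 2 / 255), dim = dim(bg))
  noisy[noisy < 0] <- 0; noisy[noisy > 1] <- 1
  fg <- subtract_background(noisy, bg, smoothing_radius = 2)
  # threshold as chosen on a real scene containing signal: add one islet
  disk <- raster_disk(100, 120, 50, 60, 15)
  frame <- noisy
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[disk > 0] <- 0.2
    frame[, , ch] <- plane
  }
  fg_scene <- subtract_background(frame, bg, smoothing_radius = 2)
  th <- EBImage::otsu(EBImage::Image(fg_scene / 255),
                      range = c(0, 1), levels = 256) * 255
  expect_gt(mean(fg <= th), 0.99)
})

test_that("biased Otsu matches the brute-force histogram oracle", {
  set.seed(5)
  x <- matrix(10, 100, 100)
  x[sample(length(x), 1000)] <- 200            # 10% bright pixels
  mask <- binarize(x, bias = 0)
  expect_identical(unname(mask), unname(x == 200))
  th <- otsu_brute(x)
  expect_true(th >= 10 && th < 200)            # oracle splits the modes too
  # bias above the maximum intensity blanks the mask
  expect_false(any(binarize(x, bias = 250)))
  # constant and all-zero images are all background, no error
  expect_false(any(binarize(matrix(0, 10, 10))))
  expect_false(any(binarize(matrix(7.5, 10, 10))))
  expect_error(binarize(array(0, dim = c(4, 4, 3))), "single-channel")
})

test_that("Otsu masks agree with brute force on random bimodal images", {
  # the between-class variance is flat across the empty gap between the
  # modes, so thresholds may differ while the masks coincide
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(5000, 40, 6), 50, 100)
    x[sample(length(x), 600)] <- rnorm(600, 180, 10)
    x <- pmin(pmax(x, 0), 255)
    mask_pkg <- binarize(x)
    mask_oracle <- x > otsu_brute(x)
    expect_gt(mean(mask_pkg == mask_oracle), 0.995)
    # both call the foreground mode foreground
    expect_true(all(mask_pkg[x > 150]))
    expect_false(any(mask_pkg[x < 55]))
  }
})

test_that("disjoint disks are labelled separately with areas near the oracle", {
  m <- raster_disk(100, 200, 50, 50, 20) + raster_disk(100, 200, 140, 50, 20)
  lab <- split_touching(m > 0)
  expect_equal(max(lab), 2)
  oracle <- sum(raster_disk(100, 200, 50, 50, 20))
  for (k in 1:2)
    expect_lt(abs(sum(lab == k) - oracle) / oracle, 0.02)
})

test_that("overlapping disks split into two regions with a deep seed threshold", {
  # centres 1.5 radii apart: the waist depth is sqrt(1 - 0.75^2) = 0.66 of
  # the distance maximum, so seeds separate for fractions above that
  m <- (raster_disk(100, 160, 60, 50, 20) +
          raster_disk(100, 160, 90, 50, 20)) > 0
  lab <- split_touching(m, dt_threshold_frac = 0.7)
  expect_equal(max(lab), 2)
  areas <- tabulate(lab[lab > 0])
  expect_lt(abs(areas[1] - areas[2]) / mean(areas), 0.2)
})

test_that("small fragments are erased by the opening step", {
  m <- matrix(0, 50, 50)
  m[20:21, 20:21] <- 1                          # 2x2 blob
  lab <- split_touching(m > 0, opening_radius = 2)
  expect_equal(max(lab), 0)
  expect_equal(max(split_touching(matrix(FALSE, 20, 20))), 0)
})

test_that("region measurement recovers disk geometry, colour and edge flags", {
  red <- hue_rgb(330)
  m <- raster_disk(160, 160, 80, 80, 50)
  frame <- mask_to_rgb(m, red)
  det <- measure_regions(matrix(as.integer(m), 160, 160), frame)
  expect_equal(nrow(det), 1)
  oracle_area <- sum(m)
  expect_lt(abs(det$area_px - oracle_area) / oracle_area, 0.01)
  expect_equal(det$ellipse_major_px, 50, tolerance = 0.03 * 50)
  expect_equal(det$ellipse_minor_px, 50, tolerance = 0.03 * 50)
  expect_equal(det$dtz_positive_px, det$area_px)   # hue 330 inside window
  expect_false(det$touches_edge)
  expect_false(det$degenerate)
  expect_equal(det$centroid_x, 80, tolerance = 0.1)
  expect_equal(det$centroid_y, 80, tolerance = 0.1)
})

test_that("region measurement recovers the axes of a rasterised ellipse", {
  m <- raster_ellipse(120, 200, 100, 60, 60, 30)
  frame <- mask_to_rgb(m, hue_rgb(60))
  det <- measure_regions(matrix(as.integer(m), 120, 200), frame)
  expect_equal(det$ellipse_major_px, 60, tolerance = 0.03 * 60)
  expect_equal(det$ellipse_minor_px, 30, tolerance = 0.03 * 30)
  expect_equal(det$dtz_positive_px, 0)             # yellow, outside window
})

test_that("edge-touching and tiny regions are flagged", {
  m <- raster_disk(60, 60, 0, 30, 10)              # clipped at the top edge
  frame <- mask_to_rgb(m, hue_rgb(330))
  det <- measure_regions(matrix(as.integer(m), 60, 60), frame)
  expect_true(det$touches_edge)
  m2 <- matrix(0L, 30, 30); m2[15:16, 15] <- 1L    # 2 px region
  det2 <- measure_regions(m2, mask_to_rgb(m2, hue_rgb(330)))
  expect_true(det2$degenerate)
})

test_that("hull/area ratio of convex regions stays within discretisation slack", {
  for (r in c(12, 25, 40)) {
    m <- raster_disk(2 * r + 20, 2 * r + 20, r + 10, r + 10, r)
    det <- measure_regions(matrix(as.integer(m), nrow(m), ncol(m)),
                           mask_to_rgb(m, hue_rgb(330)))
    ratio <- det$hull_area_px / det$area_px
    expect_gte(ratio, 1.0)
    expect_lte(ratio, 1.05)
  }
})

test_that("segmentation counts k non-overlapping disks exactly, k = 0..20", {
  bg <- array(200 / 255, dim = c(240, 320, 3))
  fg_col <- hue_rgb(330)
  centers <- expand.grid(cx = seq(30, 290, by = 52),
                         cy = seq(30, 210, by = 52))
  for (k in c(0, 1, 7, 20)) {
    m <- matrix(0, 240, 320)
    if (k > 0)
      for (i in 1:k)
        m <- m + raster_disk(240, 320, centers$cx[i], centers$cy[i], 11)
    frame <- bg
    for (ch in 1:3) {
      plane <- frame[, , ch]
      plane[m > 0] <- fg_col[ch]
      frame[, , ch] <- plane
    }
    det <- segment_frame(frame, bg)
    expect_equal(nrow(det), k)
  }
})

test_that("the segmentation pipeline is deterministic", {
  sc <- make_scene(scene_config(n_islets = 2, seed = 8, n_frames = 12))
  f <- sc$frames$frames[[10]]
  m1 <- binarize(subtract_background(f, sc$background, 2))
  m2 <- binarize(subtract_background(f, sc$background, 2))
  expect_identical(split_touching(m1), split_touching(m2))
})

test_that("total detection area never exceeds the binarised foreground area", {
  sc <- make_scene(scene_config(n_islets = 3, seed = 12, n_frames = 15))
  f <- sc$frames$frames[[12]]
  mask <- binarize(subtract_background(f, sc$background, 2))
  lab <- split_touching(mask)
  det <- measure_regions(lab, f)
  expect_lte(sum(det$area_px), sum(mask))
})
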