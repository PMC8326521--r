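test_that("equivalent spherical diameter follows the disk identity", {
  expect_equal(equivalent_diameter(pi * 100^2, 1), 200)
  expect_equal(equivalent_diameter(10000, 2.1739),
               2 * sqrt(10000 / pi) * 2.1739)
  expect_equal(equivalent_diameter(10000, 2.1739), 245.3, tolerance = 1e-3)
  expect_equal(equivalent_diameter(100, calibrate_scale(460, 1000)),
               2 * sqrt(100 / pi) * (1000 / 460))
  expect_error(equivalent_diameter(0, 1), "> 0")
})

test_that("IEq assignment reproduces the multiplier table", {
  expect_equal(assign_ieq(150)$total_ieq, 0.667)
  expect_equal(assign_ieq(c(150, 150, 175))$total_ieq,
               0.667 + 0.667 + 1.685)
  frag <- assign_ieq(30)
  expect_equal(frag$total_ieq, 0)
  expect_equal(frag$label, "fragment")
  # one diameter per bin recovers each multiplier
  mids <- c(75, 125, 175, 225, 275, 325, 375, 450)
  expect_equal(assign_ieq(mids)$contribution,
               c(0.167, 0.667, 1.685, 3.499, 6.315, 10.352, 15.833, 22.750))
  # integer-range semantics: exact 150 is in the 101-150 class,
  # 150.6 rounds up into 151-200
  expect_equal(assign_ieq(150)$label, "101-150")
  expect_equal(assign_ieq(150.6)$label, "151-200")
  expect_error(assign_ieq(-1), "> 0")
})

test_that("IEq total is monotone in any single diameter", {
  set.seed(2)
  d <- runif(30, 20, 500)
  base <- assign_ieq(d)$total_ieq
  for (i in seq_along(d)) {
    d2 <- d
    d2[i] <- d2[i] * 1.6
    expect_gte(assign_ieq(d2)$total_ieq, base)
  }
})

test_that("ellipsoid volumes match the sphere constant and hand evaluations", {
  v150 <- 4 / 3 * pi * 75^3
  expect_equal(ellipsoid_volume(75, 75, "major"), v150)
  expect_equal(ellipsoid_volume(75, 75, "minor"), v150)
  expect_equal(v150, 1.767e6, tolerance = 1e-3)
  expect_equal(ellipsoid_volume(100, 50, "major"), 4 / 3 * pi * 100^2 * 50)
  expect_equal(ellipsoid_volume(100, 50, "major") /
                 ellipsoid_volume(100, 50, "minor"), 2)
  expect_error(ellipsoid_volume(50, 100), "major >= minor")
})

test_that("major/minor volume ratio equals the axis ratio for random axes", {
  set.seed(6)
  for (i in 1:100) {
    mi <- runif(1, 5, 80)
    ma <- mi * runif(1, 1, 4)
    expect_equal(ellipsoid_volume(ma, mi, "major") /
                   ellipsoid_volume(ma, mi, "minor"), ma / mi)
    expect_gte(ellipsoid_volume(ma, mi, "major"),
               ellipsoid_volume(ma, mi, "minor"))
  }
})

test_that("track volume frame-averages and scales cubically with delta", {
  mk <- function(majors, minors) {
    d <- truth_detections(seq_along(majors) - 1L, x = 0, y = 0, area = 100)
    d$ellipse_major_px <- majors
    d$ellipse_minor_px <- minors
    list(track_id = 1L, detections = d, missed = 0L, active = FALSE)
  }
  tr <- mk(c(75, 75), c(75, 75))
  expect_equal(track_volume(tr, 1), 4 / 3 * pi * 75^3)
  # per-frame volumes 1e6 and 2e6 -> mean 1.5e6
  a1 <- (3 * 1e6 / (4 * pi))^(1 / 3)
  a2 <- (3 * 2e6 / (4 * pi))^(1 / 3)
  tr2 <- mk(c(a1, a2), c(a1, a2))
  expect_equal(track_volume(tr2, 1), 1.5e6)
  expect_equal(track_volume(tr2, 2), 8 * 1.5e6)
  # edge-touching frames are excluded; all-edge tracks give NA
  tr3 <- mk(c(75, 75), c(75, 75))
  tr3$detections$touches_edge <- c(TRUE, FALSE)
  expect_equal(track_volume(tr3, 1), 4 / 3 * pi * 75^3)
  tr3$detections$touches_edge <- TRUE
  expect_true(is.na(track_volume(tr3, 1)))
})

test_that("IEq volume is the IEq total times the 150-um sphere volume", {
  expect_equal(ieq_volume(1), v150_um3())
  expect_equal(ieq_volume(1), 1.767e6, tolerance = 1e-3)
  expect_equal(ieq_volume(0), 0)
  expect_equal(ieq_volume(0.667), 0.667 * v150_um3())
  expect_error(ieq_volume(-1), ">= 0")
})

test_that("circularity has its closed forms and clamps at 1", {
  r <- 13.7
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(4, 8), pi / 4)          # unit square
  expect_equal(circularity(100, 10), 1)            # raw > 1 clamps
  expect_gt(circularity(100, 10, clamp = FALSE), 1)
  expect_error(circularity(0, 1), "> 0")
})

test_that("solidity is area over hull area with bounded discretisation slack", {
  expect_equal(solidity(5000, 5000), 1)
  expect_equal(solidity(5000, 10000), 0.5)
  expect_equal(solidity(1020, 1000), 1)            # 2% slack clamps to 1
  expect_error(solidity(1200, 1000), "slack")
  expect_error(solidity(0, 1), "> 0")
})

test_that("a star polygon scores solidity by the shoelace/hull oracle", {
  k <- 5; R <- 50; r <- 20
  ang <- pi / 2 + seq(0, 2 * pi, length.out = 2 * k + 1)[-(2 * k + 1)]
  rad <- rep(c(R, r), k)
  x <- rad * cos(ang); y <- rad * sin(ang)
  area <- shoelace_brute(x, y)
  hull <- hull_area_brute(x, y)
  s <- solidity(area, hull)
  expect_lt(s, 1)
  expect_equal(s, polygon_area(x, y) / convex_hull_area(x, y))
})

test_that("DTZ ratio is the stained-area fraction", {
  expect_equal(dtz_ratio(100, 100), 1)
  expect_equal(dtz_ratio(0, 100), 0)
  expect_equal(dtz_ratio(50, 100), 0.5)
  expect_error(dtz_ratio(101, 100), "\\[0, area_px\\]")
  expect_error(dtz_ratio(1, 0), "> 0")
})

test_that("sample summary reports count, IEq totals and n-1 moments", {
  mk_rec <- function(d) {
    tr <- list(track_id = 1L,
               detections = {
                 det <- truth_detections(0:1, x = 0, y = 0,
                                         area = pi * (d / 2)^2)
                 det$ellipse_major_px <- d / 2
                 det$ellipse_minor_px <- d / 2
                 det
               }, missed = 0L, active = FALSE)
    tr
  }
  recs <- islet_records(list(mk_rec(100), mk_rec(150), mk_rec(200)), 1)
  rep <- summarize_sample(recs)
  expect_equal(rep$islet_count, 3)
  expect_equal(rep$diameter_um$mean, 150)
  expect_equal(rep$diameter_um$sd, 50)
  expect_equal(rep$total_ieq, 0.167 + 0.667 + 1.685)
  expect_equal(rep$ieqv_um3, rep$total_ieq * v150_um3())
  expect_equal(rep$ieqv_um3 / rep$v150_um3, rep$total_ieq)
  expect_equal(sum(rep$histograms$diameter_um$counts), 3)
  # records with bins [101-150] x2 and [151-200] x1
  recs2 <- islet_records(list(mk_rec(150), mk_rec(150), mk_rec(175)), 1)
  rep2 <- summarize_sample(recs2)
  expect_equal(rep2$total_ieq, 3.019)
  expect_equal(rep2$ieqv_um3, 3.019 * v150_um3())
  # empty input
  rep0 <- summarize_sample(islet_records(list(), 1))
  expect_equal(rep0$islet_count, 0)
  expect_true(is.na(rep0$diameter_um$mean))
})

test_that("per-record major volume dominates minor, equal only for circles", {
  mk <- function(ma, mi) {
    det <- truth_detections(0L, 0, 0, area = pi * ma * mi)
    det$ellipse_major_px <- ma; det$ellipse_minor_px <- mi
    list(track_id = 1L, detections = det, missed = 0L, active = FALSE)
  }
  recs <- islet_records(list(mk(60, 30), mk(40, 40)), 1)
  expect_gt(recs$volume_major_um3[1], recs$volume_minor_um3[1])
  expect_equal(recs$volume_major_um3[2], recs$volume_minor_um3[2])
})
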