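---
title: "Counting and measuring flowing islets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and measuring flowing islets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletflow)
```

## The measurement problem

Pancreatic islet transplantation doses are prescribed in islet equivalents
(IEq), conventionally estimated by a human operator who eyeballs diameters
of dithizone-stained tissue under a microscope. The estimate is subjective,
and it discards most of the morphological information in the sample.
`isletflow` instead analyses video of islets flowing single-file through a
microfluidic imaging channel: every islet that transits the field of view
is detected in each frame, linked across frames into one track, and
measured, yielding the count, the IEq total, two volume estimates, and
per-islet shape and purity descriptors.

The pipeline has five stages: object detection (foreground extraction),
cell segmentation, cell tracking, feature extraction and report
generation. Each stage is an exported function; `run_pipeline()` chains
them and logs one timed line per stage.

## Detection and segmentation

A single islet-free **background frame** of the same scene is required.
Frame and background are converted to luminance
(0.299 R + 0.587 G + 0.114 B, on a 0–255 scale), low-pass filtered with a
Gaussian of `segmentation.smoothing_radius` (default 2 px), and
subtracted; the absolute difference is the foreground image, so islets
darker or brighter than the channel both register. The assumption is a
static scene — illumination drift and background motion are out of scope.

The foreground is binarised at Otsu's threshold (256-bin histogram)
shifted by a signed `segmentation.otsu_bias` (default 0, in 0–255
intensity units). The bias exposes threshold tuning without abandoning
the Otsu criterion; on well-behaved scenes it stays 0. One numerical
subtlety: when the histogram gap between background and foreground modes
is empty, the Otsu objective is flat across the gap and any threshold in
it is a valid argmax; the tests therefore compare masks, not thresholds.
A constant foreground yields an all-background mask rather than an error.

Touching islets are split by a seeded watershed. The binary mask is
Euclidean-distance transformed; pixels whose distance exceeds
`segmentation.dt_threshold_frac` × (their connected component's distance
maximum) survive as seed candidates, so each blob keeps only its core.
Expressing the threshold as a per-component fraction makes the seeding
scale-invariant across islet sizes. Morphological opening with a disc of
`segmentation.opening_radius` (default 2 px) then deletes small seed
fragments — debris rather than islets. Finally, every mask pixel is
assigned to the nearest surviving seed by watershed on the inverted
distance transform, restricted to the mask.

The default fraction is 0.4. The geometry matters when choosing it: two
equal discs whose centres are $s$ radii apart develop separate seeds only
when the fraction exceeds $\sqrt{1-(s/2)^2}$ — e.g. 0.66 for $s = 1.5$.
Deeply overlapping pairs therefore need a fraction around 0.7, at the
price of discarding more of each blob's periphery from the seed (the
watershed still labels the full blob). In a flow channel, islets rarely
touch; the default favours keeping small genuine islets over aggressive
splitting.

Each labelled region yields a detection: pixel area, centroid (0-based
x = column, y = row, origin top-left), outer contour, perimeter, convex
hull area, fitted ellipse semi-axes, DTZ⁺ pixel count, and an
edge-contact flag. Regions under `segmentation.min_area` (default 5 px,
the minimum for a determined conic fit) are flagged degenerate and
ignored downstream.

Three estimator choices deserve a note:

* **Perimeter.** The naive 8-connected chain length (1 per axial step,
  √2 per diagonal) overestimates smooth contours by ≈ 5.5%, which would
  depress the circularity of a perfect disc to ≈ 0.91. The corrected
  chain estimator (axial 0.980, diagonal 1.406, −0.091 per direction
  change) is accurate to ≈ 1% for convex shapes above ~10 px radius.
* **Hull area.** The hull polygon through boundary-pixel centres never
  exceeds the pixel count for digitally convex regions (it misses the
  half-pixel rim; Pick's theorem), while the pixel count never exceeds
  the true hull area. `measure_regions()` reports the larger of the two,
  preserving hull ≥ area with near-zero bias for convex regions.
* **Ellipse fit.** Direct least-squares conic fitting (Halir–Flusser
  partitioned eigensystem) on centred contour coordinates; the ellipse
  constraint 4AC − B² > 0 is built in, and degenerate fits are flagged
  rather than propagated.

## Tracking

Detections in consecutive frames are paired by the weighted cost
$$J = w_x\frac{|x_1-x_2|}{\min(r_1,r_2)}
    + w_y\frac{|y_1-y_2|}{\min(r_1,r_2)}
    + w_a\frac{|a_1-a_2|}{\min(a_1,a_2)},$$
with $r = \sqrt{a/\pi}$ the equivalent radius of each detection's area
(the cost normalisation is not defined more precisely by the underlying
method; the equivalent radius keeps it consistent with the
equivalent-diameter convention used for sizing). The default weights
(1, 0.5, 1) encode channel flow: displacement along the channel (+x) is
informative at full weight, lateral drift is down-weighted, and area is
nearly conserved. Candidate pairs with $J \le$ `tracking.j_max`
(default 2) are consumed greedily in ascending cost; an optimal
assignment solver (`tracking.solver = "optimal"`, an O(n³) Hungarian
implementation) is available but changes nothing on well-separated
scenes. `j_max = 2` admits the expected per-frame displacement of the
default synthetic conditions (15 px advance on a ≥ 12 px radius gives
$J \approx 1.3$) while rejecting cross-channel jumps.

A track missing its match for more than `tracking.max_missed`
(default 2) consecutive frames is closed. Finalisation keeps tracks with
at least `tracking.min_track_length` (default 2) detections of which at
least one does not touch the image border — single-frame blobs are
treated as debris, and objects seen only while clipped by the border are
not measurable. The number of finalised tracks **is** the islet count.

## Physical metrics

With δ the scale (µm/px, from `calibrate_scale(marker_px, marker_um)` —
the chip embeds 1 mm and 0.1 mm markers):

* Equivalent spherical diameter: $D = 2\sqrt{A_{px}/\pi}\,\delta$.
* IEq: diameters are classified into the eight standard 50-µm classes
  (50–100, 101–150, …, 351–400, > 400 µm) with multipliers 0.167, 0.667,
  1.685, 3.499, 6.315, 10.352, 15.833, 22.750; the total IEq is the sum
  of per-islet multipliers. The printed integer ranges are read with
  round-to-nearest semantics, so class edges sit at 100.5, 150.5, … µm
  and exactly 150 µm falls in the 101–150 class. (One IEq is *defined*
  as a 150 µm islet, yet that islet scores the 101–150 multiplier 0.667:
  the multiplier is the class-average volume in $V_{150}$ units, and a
  150 µm islet sits at the top of its class. This is a property of the
  standard table, not of this implementation.) Diameters below 50 µm
  are fragments contributing 0.
* Ellipsoid-fitting volume (EFV): the fitted 2-D ellipse is revolved
  into an ellipsoid, duplicating either the major semi-axis
  ($V = \frac{4}{3}\pi M_a^2 M_i$, variant `"major"`, the default) or
  the minor one ($V = \frac{4}{3}\pi M_a M_i^2$, `"minor"`); both are
  always reported, and their ratio is exactly $M_a/M_i$. The axes enter
  as **semi**-axes — that convention is forced by consistency with the
  150-µm sphere volume $V_{150} = \frac{4}{3}\pi 75^3 = 1.767\times10^6\,
  \mu m^3$. Per-track volume is the frame average converted by δ³.
* IEqV = IEq × $V_{150}$, the volume the IEq total implies.
* Circularity $C = A/(P^2/4\pi)$, clamped to [0, 1]; rasterised convex
  shapes can exceed 1 by a few hundredths before clamping.
* Solidity = area / hull area. (The source material prints the inverted
  ratio while stating a 0–1 range with fragmented islets scoring lower;
  the standard area/hull orientation is the only one consistent with
  that statement, and is what this package computes.)
* DTZ⁺ ratio: the fraction of region pixels whose HSV hue lies in
  `purity.hue_min_deg`–`purity.hue_max_deg` (defaults 310–360 on the
  0–360° scale), i.e. dithizone-red. Per islet it is frame-averaged; the
  sample-level purity is reported both as the mean of per-islet ratios
  and as the area-weighted aggregate Σ stained / Σ area — the two answer
  slightly different questions and can diverge when purity correlates
  with size.

Per-track scalar metrics (diameter, circularity, solidity, DTZ ratio)
are averaged over non-degenerate, non-edge detections, mirroring the
frame-averaging of volume.

## The synthetic scene generator

No public islet flow videos exist, so validation rests on
`make_scene()`: elliptical islets translating along +x over a static
background, with exact ground truth (per-frame centres, semi-axes,
rendered pixel areas, stained-pixel counts). Default conditions, chosen
once as a realistic emulation of the imaging setup:

| parameter | default | rationale |
|---|---|---|
| frame size | 480 × 640 px | ≈ the ~2 mm² field of view at δ ≈ 2.17 µm/px |
| equivalent radius | 12–40 px | ≈ 50–175 µm diameters, the bulk of an islet preparation |
| axis ratio | 1–1.5 | moderately elongated islets |
| velocity | 15 px/frame | gentle syringe-pump loading; admitted by `j_max = 2` at the smallest radius |
| velocity jitter SD | 1 px, common-mode | pump pulsation advances all islets together, so staggered islets keep their spacing |
| lateral jitter SD | 1 px, stationary | independent per frame around the lane centre; a random walk would breach lane margins |
| stain fraction | 0.4–1 | free islets near 1, trapped islets lower |
| hues | 330° / 55° | inside / outside the 310–360° DTZ window |
| HSV values | 0.55 / 0.31 | equal luminance contrast against the 200-level background, so thresholding clips stained and unstained rims symmetrically |
| noise SD | 2 (0–255) | mild sensor noise |

The stained region is a parametric-angle sector: a sector of parametric
angle $2\pi f$ covers exactly the fraction $f$ of the ellipse area, so
the rendered stain fraction matches the configured one up to
rasterisation (< 0.02). Islets are laid out in lanes and staggered so no
two ever overlap (validated per frame).

What the generator does **not** emulate: lens blur and vignetting,
rolling shutter, compression artefacts, illumination drift, irregular
(non-elliptical, concave) islet boundaries, overlapping or momentarily
merging islets, and out-of-focus depth effects. Passing the validation
suite therefore demonstrates that the algorithms recover what they claim
under clean imaging conditions with known geometry; it does not certify
performance on difficult real footage, where thresholds (`otsu_bias`,
`dt_threshold_frac`, `j_max`) may need tuning.

## Validation problem sizes

The end-to-end suite runs five scenes of 50 islets each (seeds 1–5,
~150 frames per scene at the defaults) and checks: exact count recovery
(50 of 50, every ground-truth islet claimed exactly once), per-islet
diameter within 5%, EFV within 15%, DTZ ratio within 0.03, circularity
≥ 0.95 for near-circular islets (axis ratio ≤ 1.1) and solidity ≥ 0.97
for all (the rendered islets are convex). Unit suites cover each
operation against independent oracles: brute-force Otsu, exhaustive
convex hull, shoelace area, brute-force assignment enumeration, and
rasterised shapes of known geometry.

## Known limitations

* Input is a numbered PNG/TIFF frame sequence (plus a background image);
  video containers must be exploded to frames upstream.
* The background model is a single static frame; drifting illumination
  will surface as spurious foreground.
* Islets that genuinely touch for their entire transit are split only as
  well as the distance-transform geometry allows (see the seed-fraction
  discussion above).
* Hue-based purity assumes DTZ-red is the only red in the scene.
* Tracks that leave and re-enter the field of view (or vanish for more
  than `max_missed` frames) are counted twice; channel flow makes this
  rare.
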