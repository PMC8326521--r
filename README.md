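# isletflow

Islet counting and mass quantification from microfluidic flow video.

Transplantable pancreatic islet preparations are dosed in **islet
equivalents (IEq)** — conventionally estimated by an operator judging
diameters of dithizone (DTZ)-stained tissue under a microscope, a
subjective and low-information procedure. `isletflow` targets labs that
image islets flowing single-file through a microfluidic channel: it
analyses the video, counts each islet exactly once, and reports a
multi-parameter mass assessment with per-islet size, volume, shape and
purity.

## What it computes

For each islet tracked across frames (δ = µm per pixel, from the chip's
embedded scale marker):

- **Equivalent spherical diameter** D = 2√(A_px/π) · δ
- **IEq**: diameters binned into the eight standard 50-µm classes
  (50–100 … >400 µm) with multipliers 0.167, 0.667, 1.685, 3.499, 6.315,
  10.352, 15.833, 22.750; total IEq = Σ multipliers
- **Ellipsoid-fitting volume (EFV)**: the least-squares-fitted 2-D
  ellipse revolved into an ellipsoid, V = (4/3)π·Ma²·Mi (major variant)
  or (4/3)π·Ma·Mi² (minor variant), frame-averaged and scaled by δ³
- **IEqV** = IEq × (4/3)π·75³ µm³, the volume implied by the IEq total
- **Circularity** C = 4πA/P², **solidity** = A/A_hull (both in [0, 1])
- **DTZ⁺ purity**: fraction of islet pixels with HSV hue in 310–360°

Per frame, islets are segmented by background subtraction, Otsu
thresholding and a distance-transform-seeded watershed that splits
touching islets; detections are linked across frames by the weighted
cost J = |Δx|/min(r) + 0.5·|Δy|/min(r) + |Δa|/min(a), so the number of
finalised tracks is the sample count.

A synthetic scene generator (`make_scene()`) renders flowing, partially
stained elliptical islets with exact ground truth, so the entire
pipeline is validated without any real video.

## Worked example

```r
library(isletflow)

# a synthetic validation scene: 8 islets crossing a 480x640 px window
scene <- make_scene(scene_config(n_islets = 8, seed = 3))

res <- run_pipeline(
  list(scale = list(marker_px = 460, marker_um = 1000),  # 1 mm marker = 460 px
       output = list(verbosity = 0)),
  frames = scene$frames, background = scene$background)

print(res$report)
#> Islet sample report
#>   islets counted : 8
#>   total IEq      : 3.854 (IEqV 6.811e+06 um^3)
#>   total EFV      : 5.975e+06 um^3 (major-axis variant)
#>   diameter       : 102.723 +/- 28.921 um
#>   circularity    : 1.000 +/- 0.000
#>   solidity       : 1.000 +/- 0.000
#>   DTZ+ ratio     : 0.744 +/- 0.140
#>   sample DTZ+    : 0.784 (area-weighted)
```

All 8 islets are counted once. The total of 3.854 IEq means the sample
holds the islet mass of ~3.9 ideal 150-µm islets; IEqV converts that to
a volume, while EFV is the volume measured from the fitted ellipses —
the gap between the two illustrates how the coarse IEq binning
overstates volume relative to per-islet ellipsoid fitting. Circularity
and solidity are 1.0 because the rendered islets are perfect ellipses;
the DTZ⁺ ratio recovers each islet's stained-area fraction (here drawn
from 0.4–1), with the area-weighted sample purity alongside the
per-islet mean. `res$records` holds the per-islet table
(`islets.csv` when an output directory is given):

```r
head(res$records[, c("track_id", "diameter_um", "ieq_label",
                     "ieq_contribution", "dtz_ratio")], 3)
#>   track_id diameter_um ieq_label ieq_contribution dtz_ratio
#> 1        4    72.63510    50-100            0.167 0.5418545
#> 2        6    99.18100    50-100            0.167 0.7585055
#> 3        7    92.18692    50-100            0.167 0.9440476
```

To analyse real footage from the shell (numbered PNG/TIFF frames plus an
islet-free background image):

```sh
Rscript inst/scripts/isletflow.R analyze \
  --input frames/ --background bg.png --config cfg.yaml --out results/
```

writing `report.json`, `islets.csv` and `tracks.csv`. Tunables
(thresholds, tracking weights, hue window) are documented in
`?default_config` and the methods vignette
(`vignettes/isletflow-methods.Rmd`).

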