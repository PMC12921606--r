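# spheroidquant

Quantification of growth and matrix invasion of fluorescently labeled 3D
spheroids from 2D time-series images.

Spheroids (multicellular aggregates grown from tumor cell lines) embedded in
an extracellular matrix such as collagen or Matrigel are a standard in vitro
model of tumor invasion: over time, cells leave the compact spheroid core and
migrate into the surrounding gel. `spheroidquant` turns single-channel
fluorescence images of such assays — one spheroid per image, a START image
taken right after embedding plus later timepoints — into per-object and
per-image measurements of growth (core area) and expansion (number, area and
migrated distance of cells outside the core). It is aimed at cell biologists
running invasion assays who need reproducible, largely automated
quantification that still allows visual verification and manual threshold
adjustment.

## Method

For each image the pipeline computes a **spheroid-core mask** and then
detects **invading objects** outside it:

1. **Mask, "Compact" mode** — every timepoint is thresholded independently
   with minimum cross-entropy (Li) thresholding: the threshold *t* minimizes

   η(t) = −Σ<sub>g≤t</sub> g·h(g)·log μ<sub>b</sub>(t) −
   Σ<sub>g>t</sub> g·h(g)·log μ<sub>f</sub>(t)

   over the intensity histogram h(g), with μ<sub>b</sub>, μ<sub>f</sub> the
   class mean intensities; foreground is *g* > *t*. Suitable for spheroids
   that keep a sharp boundary.
2. **Mask, "Disintegrating" mode** — for spheroids that lose their boundary
   after embedding: the START image is thresholded, its mask **area** is
   recorded, and each later timepoint receives a mask of exactly that area
   covering its highest-intensity pixels (deterministic raster-order tie
   breaking). The mask's shape may evolve while its area is preserved.
3. **Automatic mode choice** — if the per-image core area of any followup
   falls below 95 % of the START core area (rapid disintegration), the
   disintegrating mode is chosen. Optionally only the largest 8-connected
   mask component is kept (default), so detached bright particles count as
   invading material.
4. **Object detection** — the extended-maxima transform (EMax): connected
   groups of local maxima whose prominence over the surrounding saddle is at
   least *h* = *dynamic* × (intensity range), computed as the regional maxima
   of the h-maxima reconstruction. Being contrast-based, it tolerates a
   nonconstant background. Components touching the mask are attributed to
   the core and dropped.
5. **Artifact exclusion** — detected objects that can contain a disk of a
   user-given radius (bubbles, debris) are flagged and removed from all
   summaries.
6. **Measurements** — per object: position, area, traced perimeter,
   circularity 4πA/P², roundness 4A/(πL²), solidity A/A<sub>hull</sub>, and
   the Euclidean distance to the nearest mask-boundary pixel. Per image: mask
   area and smoothed perimeter (opening + closing at a 15 µm detail scale, so
   small protrusions do not inflate it), object count (total and per mm of
   perimeter), total object area, mean and median distances.

A synthetic-fixture module renders calibrated spheroid time series with
planted ground truth (core, invader spots, artifacts, background ramp,
noise), so the whole pipeline is testable without any microscope data.

## Worked example

```r
library(spheroidquant)

# synthetic assay: nearly static core, 6 invaders at 24 h
fx <- write_fixture(render_fixture(scenario_presets()$suppressed_invasion),
                    "demo")
res <- run_pipeline(list(
  start_path = fx$start_path, followup_paths = unname(fx$followup_paths),
  pixel_size_um = fx$pixel_size_um, labels = c("START", "24h"),
  output_dir = "demo_out"))
res$mode      # "compact" (chosen automatically: the core does not shrink)
res$summary
```

`demo_out/summary.csv` (one row per timepoint):

```
"timepoint_label","mode","mask_area_um2","mask_perimeter_um","n_objects","n_objects_per_mm","total_object_area_um2","mean_distance_um","median_distance_um","n_excluded_artifacts","threshold_used","emax_dynamic","artifact_radius_um","detail_um"
"START","compact",106212,1211.89,0,0,0,NA,NA,0,12355,0.001,0,15
"24h","compact",112106,1242.89,6,4.82746,1267.61,56.4253,56.13,0,12337,0.001,0,15
```

Reading: the core grew from 0.106 to 0.112 mm² (growth), no object lies
outside the mask at START (as it must immediately after embedding), and at
24 h six objects totalling 1268 µm² sit at a mean distance of 56 µm from the
core boundary (expansion). `objects_24h.csv` lists each object's centroid
(0-based x = column, y = row), area, perimeter, shape descriptors and
distance; `overlay_24h.png` shows the mask boundary in red and the detected
objects in green for visual verification. If the mask looks wrong, re-run
with per-image `threshold_overrides` — the non-interactive equivalent of
adjusting the threshold in a dialog.

The same driver is available from a shell:

```sh
inst/scripts/spheroidquant run --start demo/START.tif --followups demo/24h.tif \
    --pixel-size 2.27 --mode auto --emax-dynamic 0.001 --out demo_out
```

## Conventions

- Pixel coordinates in tables are 0-based with (x, y) = (column, row).
- µm-per-pixel calibration is an explicit required parameter.
- Input: 8/16-bit grayscale TIFF or PNG (one informative channel).
- All component labeling uses 8-connectivity; traced perimeters count axial
  steps as 1 and diagonal steps as √2.
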