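---
title: "Quantifying spheroid growth and invasion from 2D fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid growth and invasion from 2D fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidquant)
```

## The measurement problem

A fluorescently labeled spheroid embedded in an extracellular matrix is
imaged at a START timepoint (immediately after embedding, before any
migration) and at later timepoints. Two quantities are of interest:

* **growth** — the change in area of the compact spheroid core, and
* **expansion** — the number, total area and migrated distance of cells (or
  cell clusters) found outside the core, regardless of whether they got
  there by invasion, proliferation or both.

Both require a per-image binary **mask** of the core and a **detector** for
objects outside it. The package implements these as a deterministic,
semiautomatic pipeline: all parameters are explicit, every run writes
overlays for visual verification, and re-running with adjusted thresholds
replaces interactive dialog loops.

## Core mask

**Compact mode.** Each image is thresholded independently by minimum
cross-entropy (Li) thresholding on its intensity histogram; foreground is
strictly greater than the threshold. No information crosses timepoints, so
images of different sizes or with drifting illumination are handled
independently. The threshold search is an exact arg-min of the
cross-entropy objective over every observed intensity level (the objective
is piecewise constant between levels, so this equals a scan over all
levels); ties go to the smallest level. A constant image has no contrast
and is rejected.

**Disintegrating mode.** Rapidly invading lines keep a compact core only at
START. The assumption this mode rests on: *individual cells that left the
spheroid are less fluorescent than the core*, because they no longer stack
in depth. The START mask is computed as in compact mode and its pixel area
recorded; each later timepoint then gets a mask of exactly that area
covering its brightest pixels. The tie rule at the cut intensity is a
raster-order fill (top-left first), which makes the area exact and the mask
reproducible. The mask's shape is free to evolve — important for cores that
deform — while its area is fixed by construction.

**Largest component.** With the (default) `keep_largest` option, only the
largest 8-connected component of each mask survives. In disintegrating mode
this deliberately breaks the fixed-area property of followup masks:
detached bright debris is expelled from the core and subsequently counted
as invading material. Area ties are broken toward the component whose first
pixel comes earliest in raster order, keeping the pipeline a total
function.

**Automatic mode choice.** All images are probed with the compact
segmentation (plus largest-component retention); if any followup core area
drops below `1 - shrink_tol` (default 0.05) of the START area, the
disintegrating mode is chosen. Shrinkage of a healthy compact spheroid
between timepoints is biologically implausible, so the 5 % band only
absorbs segmentation noise; the probe areas are attached to the result and
echoed in the run log. All followups are inspected, not just the first —
disintegration that begins late is still disintegration.

## Detecting objects outside the mask

Objects are connected groups of local intensity maxima found by the
**extended-maxima transform**: a maximum survives iff its prominence over
the surrounding saddle is at least `h = dynamic × intensity range`,
computed as the regional maxima (8-connectivity) of the morphological
reconstruction of `image - h` under `image`. Because `h` is relative and
the reconstruction climbs any smooth background, detection tolerates the
nonconstant backgrounds common in real fluorescence images, and is exactly
invariant to adding a constant to all intensities.

The **intensity range** defaults to the observed `max - min` of each image
rather than the theoretical bit-depth range; this keeps a given `dynamic`
portable between 8- and 16-bit exports of the same data (a `range_from`
switch selects the bit-depth convention instead). The default
`dynamic = 0.001` is the value that, on typical data, detects nearly all
objects at followup timepoints while leaving the START image empty; it
should be chosen once per dataset by inspecting START overlays (START must
show no objects — anything detected there is a contaminant) and then held
fixed for all evaluations of that dataset.

Components with any pixel inside the mask are attributed to the core and
dropped entirely rather than clipped — clipping would corrupt the shape
descriptors. A component covering the whole image marks no localized
maximum and is discarded; a flat image yields none.

**Artifact exclusion.** Bubbles and debris are typically much larger than
cells. An object is flagged iff it can contain a digital disk of the given
radius, decided by erosion of its pixel set with the disk structuring
element `{(dr,dc): dr² + dc² ≤ r²}` (radius rounded to pixels, minimum 1;
radius 0 disables the step). Flagged objects stay in the detailed table but
leave every count and summary statistic.

## Measurements

* **Perimeters** are traced along 8-connected Moore contours: axial steps
  count 1 pixel, diagonal steps √2. A single pixel has no steps and reports
  perimeter 0. For the *mask* perimeter the mask is first smoothed by
  opening + closing with a disk of radius `detail_um / 2` (default
  `detail_um` = 15 µm, the midpoint of the 10–20 µm scale at which surface
  detail stops being meaningful for a spheroid outline), so thin
  protrusions do not inflate the normalization length. Smoothing affects
  the perimeter only; areas and distances always use the raw mask.
* **Distances** run from the object's centroid (default; `"edge"` uses the
  nearest object pixel instead) to the nearest mask boundary pixel — a mask
  pixel with a background 4-neighbor, with out-of-image counting as
  background. Measuring from the boundary rather than the mask centroid
  keeps distances meaningful for irregular, elongated or lobed cores. The
  centroid default matches the single "position" reported per object; the
  flag exists because either convention is defensible.
* **Shape descriptors** follow the particle-analysis conventions:
  circularity 4πA/P² (capped at 1 — digitization can push small objects
  above it), roundness 4A/(πL²) with L the major axis of the
  second-moment-matched ellipse (each pixel contributes a unit square's
  1/12), and solidity = pixel area over the area of the convex hull of the
  pixel squares' corners (equivalently, of the union of pixel squares).
  Under this hull convention a digitized disk's jagged rim leaves genuine
  shallow concavities, so a radius-30 disk reports solidity ≈ 0.97, not
  1.0; axis-aligned rectangles report exactly 1.0. Single-pixel objects
  report 1.0 for all three by convention.
* **Summary per image**: mask area, smoothed mask perimeter, object count
  (total and per **mm** of smoothed perimeter — the unit is printed in the
  header), total object area, mean and median distances, number of excluded
  artifacts, and an echo of every parameter, making output tables
  self-documenting.

### Distance semantics in disintegrating mode

The disintegrating-mode mask preserves the START area, so its boundary lies
outside the instantaneous core of a shrunken spheroid — intentionally: it
represents where core material is still concentrated at the original
scale. Distances reported in that mode are therefore measured from a wider
boundary than the visible core rim. When distance fidelity against the
true current core matters (as in the package's ground-truth tests), the
per-image compact mask is the right reference; the tests use it for
exactly that comparison, while recovery and counting run on the
disintegrating pipeline as users would.

## The synthetic fixture generator

`fixture_spec()` / `render_fixture()` draw a calibrated time series with a
planted-ground-truth registry: a core disk with a Gaussian-profile soft
edge, invaders as isotropic Gaussian spots (σ ≈ a cell radius, matching the
local-maxima detection model and making prominence analytically
controllable), optional uniform bright disks as bubbles, a linear
background ramp, seeded additive Gaussian noise, and a disintegration
phenotype (shrinking core plus detached rim fragments). The START image
contains the core only, since no migration can have occurred at embedding;
invaders must lie at least 3σ outside the core, which the constructor
enforces.

The presets encode the study conditions used throughout the tests: 400×400
px at 2.27 µm/px (a 5× widefield scale), 16-bit, core plateau 60000
counts, invader spots of 200 counts peak amplitude and σ = 10 µm,
background 500 counts with a 40-count ramp (20 % of the invader signal)
and noise of 6 counts (3 % of the invader signal). The intensity scale is
deliberately asymmetric: the bright core dominates the image range, so the
default detection prominence `h = 0.001 × range ≈ 60` counts sits near
10 noise standard deviations — fluorescence imaging of a densely labeled
core next to single cells genuinely produces such ratios, and it is the
regime in which a small relative dynamic cleanly separates cells from
noise and background ramp (whose maxima have prominence ≈ ramp/2 + a few
σ ≈ 40 counts here). Scenario sizes (20 invaders for the invasive
phenotype, 6 close-in invaders for the suppressed one, one 60 µm bubble)
were chosen once as representative of the assay and are not tuned.

What the generator does **not** emulate: optics (no PSF convolution or
vignetting), Poisson photon statistics (a Poisson option exists but is off
by default so oracle tests stay exact), cell shape (invaders are round
spots), movement of individual cells between timepoints, or out-of-focus
light from the 3D gel. Passing tests therefore demonstrate algorithmic
correctness and robustness to the modeled effects (nonconstant background,
noise, disintegration, artifacts) — not performance on any particular
microscope's data, where the dynamic and artifact radius still need the
one-time visual calibration described above.

## Numerical choices and degenerate inputs

* All tie rules (fixed-area fill, largest component, component label
  order) are raster-scan total orders, so identical inputs give
  bit-identical masks and tables; CSV floats are written with 6 significant
  digits to keep repeated runs byte-identical.
* Foreground is strictly `> t`; 8-connectivity everywhere (the usual
  particle-analysis default).
* Empty masks: legal after an above-maximum threshold override (warning);
  perimeter 0 with a warning; distances are errors (no boundary exists).
* A threshold override above the maximum yields an empty mask rather than
  an error, because it can arise legitimately during manual threshold
  exploration.
* Reconstruction runs on floating-point intensities (the prominence `h` is
  generally fractional); regional-maxima plateaus compare values exactly,
  which is safe because reconstruction only propagates existing values.

## Known limitations

* Detection marks local maxima, not full cell segmentations: a cell with
  several maxima can split, a tight cluster can merge into one object, and
  object areas underestimate true fluorescent extent. Counts and distances
  are the robust outputs; per-object areas are indicative.
* One spheroid per image is assumed; multiple cores would require cropping
  (a rectangular region-of-interest crop is available in
  `detect_objects()`).
* The disintegrating mode presumes the core remains the brightest
  structure; a followup whose invaders outshine the core would corrupt the
  fixed-area mask.
* Statistics across biological replicates (rank tests etc.) are downstream
  of this package and intentionally out of scope.
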