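---
title: "Quantifying particulate embolic distribution in microCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying particulate embolic distribution in microCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embolimetry)
```

## The problem

Transarterial embolization occludes target vasculature by injecting
particulate embolic agents — here, radiopaque microspheres of 75–100 µm
diameter. How the operator injects (a steady *continuous* push to stasis,
versus *pulsed* 1 ml boluses separated by pauses) may change how deep into
the distal vascular bed the particles travel. With radiopaque beads, a
whole explanted organ can be imaged by microCT at 0.1 mm isotropic
resolution and the full three-dimensional particle distribution quantified
without destructive sectioning.

`embolimetry` implements that quantification pipeline for paired
kidney-embolization experiments:

1. **volio** — minimal NIfTI-1 / multi-page TIFF volume I/O with voxel
   spacing metadata (no R package in this toolchain reads NIfTI, so a
   narrow reader/writer is built in);
2. **phantom** — a synthetic ellipsoid-kidney generator with
   regime-dependent microsphere deposits and retained ground truth;
3. **segmentation** — deterministic threshold-plus-size-filter extraction
   of the embolic signal, and 3D connected-component labeling;
4. **stratify** — depth-stratified cortical shell masks by Euclidean
   surface erosion;
5. **quantify** — intersection counts, embolization efficiency, percent
   embolized cortex, per-region particle counts, volume ratios;
6. **stats** — paired t and exact Wilcoxon signed-rank tests with
   median/range summaries;
7. **study_runner** — the full paired design end to end.

## The model and its conventions

### Geometry

Volumes are 3D grids with a single isotropic spacing in mm; the physical
center of voxel $(i,j,k)$ (1-based) is
$\mathrm{origin} + ((i,j,k) - 0.5)\,s$. Grids from one analysis must share
shape and spacing exactly; nothing is ever resampled implicitly.

### Cortical stratification

"Eroding the kidney by $d$ pixels from the surface inwards" is interpreted
as **Euclidean distance-transform thresholding**: the surface distance
field assigns every foreground voxel its exact Euclidean distance (voxel
units) to the nearest background voxel center, and the eroded interior
keeps voxels with distance $> d$. The cortical shell at depth $d$ is the
complement within the organ — exactly the voxels within $d$ pixels of the
surface. The alternative reading, $d$ iterations of a box/cross structuring
element, carves anisotropic chamfer geometry and was rejected; the ball
metric matches "distance from the surface inwards" literally and has an
exact brute-force oracle (tested). The strict inequality puts
boundary-distance voxels in the shell, so $\mathrm{shell}(d)$ and
$\mathrm{eroded}(d)$ partition the organ for every $d$, and shells nest
monotonically with depth. At 0.1 mm resolution, 50 px and 100 px are 5 and
10 mm of physical depth.

The distance transform is the exact separable squared-distance algorithm
(lower-envelope-of-parabolas), implemented in C++; foreground seeds use a
large finite constant rather than infinity so envelope intersections of two
seeded parabolas remain well defined.

### Segmentation and particle counting

The original workflow used an interactive pixel classifier; this package
substitutes a declared deterministic rule — global intensity threshold,
then removal of connected components below a minimum voxel count.
Radiopaque beads are engineered to be high contrast, so the substitution
costs little and buys exact reproducibility. A **particle** is a connected
component of the segmented mask under 26-connectivity (sub-voxel beads can
touch diagonally after noise; splitting one bead into two counts is the
worse failure mode). Beads that merge into one component count once — the
counting convention is declared rather than inferred, since no counting
rule is published for the original data. A component is assigned to a
region (shell or interior) by its rounded voxel centroid, which makes
per-region counts partition the total.

### Quantification metrics

* **Embolization efficiency**: intersecting voxel count of the segmented
  embolic mask with a region, divided by kidney volume in ml — voxels per
  ml. Voxels, not components, are counted here (the binary-volume
  intersection reading).
* **Percent embolized cortex**: $100 \cdot |\text{embolic} \cap
  \text{shell}| / |\text{shell}|$. The denominator is the shell's own
  volume — "percentage of the embolized cortex" read as a fraction of
  cortex. The source text never states its denominator, so the whole-organ
  denominator is available behind `cortex_denominator = "whole"`.
* **Kidney volume**: defaults to the mask-derived volume
  ($\text{voxels} \times s^3/1000$); the sonographic ellipsoid estimate
  $V = (\pi/6) LWH$ is available as an alternative normalizer, since the
  original volumes were measured by pre-embolization ultrasound and the
  normalization source is unstated.

### The phantom: a stated world, not a fitted one

No scans from the original experiment are deposited, so the synthetic
module emulates the stated experimental conditions:

* ellipsoid kidneys with axis proportions 66.4 : 50 : 45 (a 78 ml
  median-sized porcine kidney at the default full scale), volumes drawn
  per subject from the observed 46–138 ml range;
* 0.1 mm isotropic voxels;
* beads of 75–100 µm diameter (radii 37.5–50 µm), sub-voxel at this
  resolution — rasterization marks every voxel whose center a bead covers
  and always at least the voxel containing the bead center, so beads
  remain detectable;
* per-kidney particle counts Poisson-distributed with means 3,400
  (continuous) and 3,100 (pulsed), matching the ~3,000–3,700 per-kidney
  counts reported;
* injected embolic volume per kidney uniform over 12–20 ml (continuous)
  and 8–22 ml (pulsed), the reported ranges.

Injection regimes are modeled **phenomenologically as penetration-depth
distributions**, not hemodynamically: each particle's depth below the
surface follows an exponential with mean `depth_scale_px` (continuous 40,
pulsed 60), truncated at the deepest interior voxel; the particle is placed
uniformly among voxels of the nearest integer depth bin of the same
distance field the stratification step uses, so generator and analyzer
share one geometry and recovery tests can be exact. The scales were chosen
once so that the direction and rough size of the continuous-vs-pulsed
contrast match the reported outcome (more particles, shallower deposition
for continuous); the source provides outcomes, not transport physics, and
these parameters are configurable.

Within a subject, the two kidneys' volumes are jittered ±10% around one
subject-level draw: a pig's kidneys are close in size, and that similarity
is what makes the paired design informative. Independent draws across a
3× volume range would have buried the within-subject contrast in
between-kidney size variance.

Noise is independent zero-mean Gaussian, clamped at zero, with default
σ = 30 against a bead/background contrast of 300. No SNR figures exist for
these beads on this scanner, so the noise level is **calibration-free**: it
is set at 10% of contrast, where segmentation is still essentially exact
(≈ 5σ margins) but the noise path is genuinely exercised. Green phantom
tests therefore establish pipeline correctness — geometry, counting,
bookkeeping — not robustness to real scanner artifacts (beam hardening,
streaks, partial-volume blur are all out of scope and unmodeled).

### Statistics

Each subject acts as its own control, so all comparisons are paired with
$n = 7$. The paired t statistic is $\bar d / (s_d/\sqrt n)$ with a
two-sided $t_{n-1}$ p-value. The Wilcoxon signed-rank test is implemented
in-house with an **exact** small-$n$ mode because at $n = 7$ the normal
approximation is dubious and the original analysis does not say which was
used: ties receive midranks, zero differences are dropped (the classical
policy), and the two-sided p-value is the probability that $|W|$ meets or
exceeds the observed value under all $2^n$ equally likely sign assignments
of the observed ranks. The null distribution is computed by convolving the
per-rank characteristic polynomials over the integer support of twice the
positive-rank sum — algebraically identical to full enumeration, and the
test suite checks it against a literal $2^n$ enumeration oracle. Exact
p-values are therefore multiples of $2^{-n}$; the attainable test size just
below 0.05 at $n = 7$ is $6/128 \approx 0.047$. Raw two-sided p-values are
reported without multiplicity correction, mirroring the handful of
prespecified contrasts in the original report.

## Numerical and design choices

* **Degenerate inputs** error loudly: empty masks for sampling, masks
  filling the whole grid for distance transforms, zero-variance differences
  for the t test, all-zero differences for the Wilcoxon, empty shells for
  percentages, non-increasing depth lists.
* **Seeding**: a study is reproducible from its configuration and one
  integer seed; each kidney uses the child seed
  $\mathrm{seed} + 10\,\mathrm{subject} + \mathrm{side}$, so any kidney can
  be regenerated in isolation. Replicate studies should use seeds spaced by
  ≥ 100 to keep child-seed streams disjoint.
* **Ties** in depth-bin snapping go to the shallower bin; component
  centroids use banker's rounding and are clamped to the grid.
* **File formats**: NIfTI-1 is canonical (masks as uint8, volumes as
  float32 — lossless for binary and integer data; spacing is snapped back
  from float32 to 7 significant digits on read). TIFF stacks are read-only
  and require an explicit spacing because TIFF carries no reliable 3D
  spacing metadata.
* **Scaled-down testing**: simulation tests run kidneys at ~1/4 linear
  scale (~1–1.6 ml) with the pixel-denominated depth, regime and noise
  defaults untouched; the replicate-heavy direction-of-effect study
  additionally uses near-spherical phantoms (0.8–1.0 ml), the most
  voxel-economical shape that keeps 50-px shells a proper subset of the
  organ. The properties being checked — partition algebra, ground-truth
  recovery, test size, direction of the regime contrast — are scale- and
  eccentricity-free (ellipsoid eccentricity is exercised by the
  stratification tests); full-scale 46–138 ml kidneys at 0.1 mm are
  ~150M-voxel grids and are supported by the same code but not exercised
  in CI-sized runs.

## Known limitations

* The kidney is a single ellipsoid: no hilum, collecting system, or
  anatomical cortex/medulla boundary; depth from the outer surface is a
  geometric proxy for "cortical".
* Merged beads under-count particles; there is no watershed splitting.
* No hemodynamics: stasis endpoints, pulse-frequency effects and operator
  variability are outside the model, which is why the synthetic study can
  only reproduce the *direction* (and configured rough size) of the
  published contrast, never its exact medians or p-values — those depend on
  the undeposited scans.
* The published per-subject "100-micron mask" counts are far smaller than
  the 50-mask counts, which contradicts shell nesting; whatever convention
  produced them is not recoverable from the text, and this package's nested
  convention will not reproduce them.
* The published mean embolic/kidney ratio (0.20 vs 0.16) is not the ratio
  of the published medians (14.0/78.1 ≈ 0.179); it is presumably a mean of
  unprinted per-kidney ratios and is treated as input arithmetic only.

## A worked example

```{r example, eval = FALSE}
library(embolimetry)

# scaled-down paired study: 7 subjects, both regimes, full pipeline
cfg <- study_config(kidney_volume_ml_range = c(1.0, 1.6),
                    depths_px = c(50L, 100L))
res <- run_study(cfg, seed = 17)
print(res)
write_results(res, "quant.csv", "summary.json")

# the in-paper arithmetic the acceptance tests pin down
sum_particle_counts(c(3688, 3118))   # 6806 particles, continuous
sum_particle_counts(c(3049, 3125))   # 6174 particles, pulsed
percent_difference(0.20, 0.16)       # 25% ratio contrast
```
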