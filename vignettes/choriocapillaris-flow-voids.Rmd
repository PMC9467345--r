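---
title: "Quantifying choriocapillaris flow voids from averaged en face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow voids from averaged en face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

The choriocapillaris (CC) is the capillary monolayer directly beneath the
retinal pigment epithelium. On en face OCT angiography it appears as a fine
bright meshwork punctured by small dark *flow voids* — regions with no
detectable flow signal. In pachychoroid-spectrum disease, and in its
presumed earliest stage, pachychoroid pigment epitheliopathy (PPE), the CC
is thought to be diffusely ischemic; the question this pipeline addresses is
twofold:

1. Do PPE eyes show more flow-void area than healthy eyes of the same age?
2. Is the flow deficit co-localized with *pachyvessels* — the pathologically
   dilated outer choroidal veins that are the anatomical signature of
   pachychoroid disease — or spread across the field regardless of vessel
   position?

A single 3 × 3 mm CC en face frame is dominated by speckle; the standard
remedy is to capture ~9 frames, register them rigidly, and average, which
suppresses speckle variance roughly as 1/N and makes the meshwork, and
therefore the voids, quantifiable. Registration is estimated on the paired
superficial-capillary-plexus (SCP) frames — whose large vessels are
high-contrast landmarks — and the same transforms are re-applied to the CC
frames, which carry too little structure per frame to register on their own.

The per-eye processing chain is:

```
register (SCP) -> average (CC) -> Phansalkar threshold -> invert
    -> connected components -> {count, total area, mean size}
choroid en face OCT -> Phansalkar threshold -> invert -> pachyvessel mask
flow-void mask x pachyvessel mask -> overlap percentages + composite image
```

```r
library(ccflow)
scene <- generate_scene(seed = 1)                       # ground truth anatomy
stack <- render_octa_stack(scene, acquisition_params()) # 9 speckled frame pairs
choroid <- render_choroid_oct(scene)
eye <- run_eye(stack, choroid)
eye$metrics   # n_voids, total_area_mm2, mean_size_um2
eye$overlap   # pachyvessel portion, void-over-vessel share
```

## Binarization model

Flow voids are extracted by Phansalkar local adaptive thresholding, which
was designed for dark objects in low-contrast images. For a pixel with
neighborhood mean $m$ and (population) standard deviation $s$, the threshold
on $[0,1]$ intensities is

$$T = m\left(1 + p\,e^{-q m} + k\left(\frac{s}{r} - 1\right)\right)$$

with the conventional constants $p = 2$, $q = 10$, $k = 0.25$, $r = 0.5$ and
a circular window of radius 15 px. A pixel is *bright signal* iff its value
strictly exceeds $T$; the inverted mask is the flow-void (or, on the
choroidal slab, pachyvessel) mask. Choices the method description leaves
open, fixed here:

* **Window**: disk of radius 15 px (square available for comparison).
* **Borders**: mirror (symmetric) padding.
* **Tie-break**: a pixel exactly at $T$ is background, so the all-zero
  image binarizes to all-background.
* **SD convention**: population SD over the window.

The implementation computes $m$ and $s$ by FFT convolution; a naive
per-pixel double loop serves as its oracle in the tests and must agree
mask-exactly.

Connected components use 8-connectivity (the usual particle-analysis
convention; 4 by flag), voids touching the field edge count with their
visible area, and no minimum-size filter is applied by default — both
filters exist in the configuration but are off, since the original analysis
states none. The three per-eye metrics satisfy
`n_voids * mean_size_um2 * 1e-6 == total_area_mm2` by construction.

## Registration model

Rigid transforms (translation + rotation about the field centre) are the
minimal model that beats the inter-frame jitter of repeated captures.
Translation is estimated by phase correlation, refined to 0.05 px by a local
upsampled DFT of the cross-power spectrum; rotation by a coarse grid plus
golden-section search (±2° by default) maximizing the correlation peak.
Frames are warped with bilinear interpolation under the inverse transform;
out-of-field pixels are flagged invalid and excluded from the average rather
than zero-filled, which would otherwise create dark rims that bias the
thresholding. Frame quality is the peak normalized correlation after
alignment — the software analogue of the device's signal-strength score —
and frames under `min_quality` (default 0.5) are dropped from the average,
mirroring the exclusion of captures with blink artifacts or poor fixation.
The reference frame defaults to the first of the stack.

## Cohort statistics

Group comparisons follow clinical-table conventions:

* **Unpaired t-test**, Student (pooled) by default, Welch by flag. Groups
  may be raw vectors or `(n, mean, sd)` summaries; both paths agree exactly
  when the summaries derive from the raw data, so published tables can be
  re-tested without individual-level data.
* **Chi-square (2×2)** for the sex ratio, without Yates correction by
  default — the convention under which the published sex comparison
  reproduces; correction by flag.
* **Pearson correlation** with the t-transform p-value.
* **"Adjusted for age and sex"** is operationalized as the partial
  correlation between the 0/1 group indicator and the metric, controlling
  age and 0/1-coded sex: both variables are residualized on `[1, age, sex]`
  and the residual correlation is tested on $n - 2 - k$ degrees of freedom.
  With no covariates this reduces exactly to the Pearson test.

All p-values are two-sided; no multiple-testing correction is applied
(matching the original analysis).

## The synthetic-data generator

No raw images are publicly available for this kind of study, so the
generator is a first-class module that emulates the acquisition at the
published study conditions, with stored ground truth for every stage.

**Scene.** The meshwork is a jittered-grid (blue-noise) Voronoi lobule
tessellation: the band around cell boundaries is perfused capillary, the
eroded cell interiors are the flow voids — a geometry motivated by the
lobular organization of the CC, where each lobule drains to a central
venule. The band half-width is solved by bisection so the realized void
fraction matches the target exactly up to pixel quantization, and the seed
count is corrected by a short fixed-point iteration so the realized mean
void size lands near its target (small cells vanish under the erosion,
which would otherwise inflate mean size by ~45%). Pachyvessels are 2–5
smoothed random-walk ribbons, 150–400 µm wide, entering from the border,
with a global width scale bisected toward the target area fraction. Voids
are placed independently of vessels, so the expected void-over-vessel share
equals the vessel area portion — the "no co-localization" null the study
design probes.

**Acquisition.** Each frame is the scene's base reflectance times i.i.d.
multiplicative gamma speckle (mean 1, shape `speckle_shape`), rigidly
displaced by a per-frame random transform shared bit-exactly between the CC
frame and its SCP reference — the property registration exploits. Gamma is
chosen for its closed-form moments (variance of a frame at a pixel with
base reflectance $b$ is $b^2/\text{shape}$), which the tests verify by
Monte Carlo.

**Defaults and why.** The raster is 300 × 300 px for the 3 mm field
(10 µm/px, the A-scan pitch of 3 × 3 mm scans on swept-source devices; the
source study does not state export dimensions, so this is recorded as an
assumption in the configuration). Speckle shape defaults to 12: en face
slab images are not fully developed speckle (shape 1) because the thin slab
is already axially compounded by the device; shape 12 gives a single-frame
speckle contrast of ~0.3 and a granular single frame that cleans up with
9-frame averaging, matching the qualitative single-vs-averaged contrast the
method depends on. Capillary reflectance 0.55 and flow-void reflectance
0.20: voids are dark gray, not black, on real OCTA (noise floor and
multiple scattering), and this matters quantitatively — the Phansalkar
threshold sits above the edge-transition midpoint, so with near-black voids
the sub-pixel rim blur introduced by registration and bilinear averaging
would dilate every ~8-px void and inflate total void area by ~20%, whereas
at realistic void reflectance the pipeline is an approximately unbiased
estimator of the true void area. Per-frame jitter defaults to SD 2 px
translation and 0.3° rotation; quality scores are drawn from [0.8, 1],
the analogue of accepting only captures scoring ≥ 8/10. On choroidal en
face OCT the stroma is 0.8 and venous lumens 0.1 (strongly hyporeflective),
plus additive Gaussian noise (SD 0.05).

**Cohort.** Per-group zero-truncated normal draws whose defaults are the
published group summaries (PPE n = 32: age 62.5 ± 8.6 y, SFCT 374.5 ± 81.5
µm, 1483 ± 154 voids, 1.16 ± 0.18 mm², 790 ± 144 µm², 25 M / 7 F, 25/32
with pachyvessels in the field; controls n = 30: 65.2 ± 9.9 y,
248.7 ± 35.3 µm, 1826 ± 319 voids, 0.91 ± 0.16 mm², 520 ± 138 µm²,
18 M / 12 F). Truncation at zero is negligible at these means (≥ 5 SD from
zero) but guarantees positive areas and ages. The RPE-to-vein distance uses
the pachyvessel / non-pachyvessel split summaries (64.0 ± 19.6 vs
107.2 ± 25.9 µm); since the generator draws it per group rather than per
pachyvessel status, the PPE default is their 25:7 mixture mean.

**What the generator does *not* emulate** — and hence what passing tests do
not establish about device data: projection and motion artifacts beyond
rigid transforms, RPE pathology texture, depth-dependent signal loss,
spatially correlated speckle, the device's proprietary slab segmentation,
and any systematic difference between the synthetic lobule geometry and
real CC anatomy. Results on synthetic eyes validate the *pipeline's*
correctness and calibration, not device-level accuracy.

## Numerical choices and degenerate inputs

* All generators are pure functions of `(seed, parameters)`; the study
  driver `run_all()` derives every per-eye seed from the single config seed,
  and two runs with the same seed produce byte-identical artifact manifests.
* Registration of a constant image is refused (correlation undefined), as
  are zero-variance inputs to the correlation tests, zero-margin 2×2
  tables, both-groups-constant t-tests, and overlap ratios on an empty
  void mask.
* A scaled-down raster keeps void *fractions* (not absolute areas) at their
  3-mm-field values, so quick runs remain statistically faithful.
* Mirror padding, strict-`>` thresholding and population SD are fixed
  conventions shared by the implementation and its oracles.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
study at 300 × 300 px with 3 frames per eye for the 62-eye cohort (the
full-resolution 9-frame configuration is used for the 20-eye parameter
recovery study and per-eye examples); registration and averaging
benchmarks use 128-px scenes over 50 seeds, statistical calibration uses
2,000 null replicates per test, and the power check at the published group
parameters uses an exact noncentral-t oracle plus a 400-seed simulation.
These sizes were chosen so each analysis settles its Monte-Carlo error well
inside the tolerances it is checked against.

## Known limitations

* Rotation search is a 1-D correlation-peak optimization; it is reliable
  for the sub-degree jitter of fixating eyes but not for large torsions.
* The Voronoi-lobule void geometry has a narrower size distribution than
  real CC flow voids; count-based comparisons between synthetic groups are
  meaningful, but absolute counts should not be read as device-equivalent.
* The pipeline measures what the threshold sees: on noisy single frames
  (`n_frames = 1`) the void metrics are dominated by speckle artifacts, and
  the pipeline reports them as such rather than refusing to run.
* Partial correlation assumes linear covariate effects; with a 0/1 group
  indicator it is the standard operationalization of "adjusted for age and
  sex" but is not a substitute for a full regression model.
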