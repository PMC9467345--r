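# ccflow — choriocapillaris flow-void quantification from en face OCTA

`ccflow` is an R package plus analysis workflow for quantifying
choriocapillaris (CC) flow deficits from en face optical coherence
tomography angiography, built for the study design that compares
pachychoroid pigment epitheliopathy (PPE) eyes against healthy controls and
asks whether the flow deficit co-localizes with pachyvessels (dilated outer
choroidal veins).

It is aimed at ophthalmic image-analysis researchers who need the full
measurement chain as tested, reusable code:

1. **Registration & averaging** — rigid alignment of ~9 repeated 3 × 3 mm CC
   frames, estimated by phase correlation (0.05 px sub-pixel refinement,
   optional rotation search) on the paired superficial-capillary-plexus
   frames, then pixelwise averaging with quality gating; speckle variance
   drops ~1/N.
2. **Binarization** — Phansalkar local adaptive thresholding,
   `T = m (1 + p e^{-q m} + k (s/r − 1))` over a radius-15 disk
   (p = 2, q = 10, k = 0.25, r = 0.5 on [0, 1] intensities), then mask
   inversion so flow voids (or pachyvessel lumens on the choroidal slab)
   become foreground.
3. **Quantification** — 8-connected components of the void mask give the
   per-eye triple: number of voids, total void area (mm²), mean void size
   (µm²); overlaying the pachyvessel mask gives the vessel area portion and
   the share of void area overlying vessels (%), plus the red/green/yellow
   composite image.
4. **Cohort statistics** — unpaired t-tests (Student/Welch, raw data or
   published n/mean/SD summaries), 2×2 chi-square, Pearson correlation, and
   partial correlation for age/sex-adjusted p-values; rendered as the
   three clinical-style group tables.
5. **Synthetic data** — a ground-truthed generator (Voronoi-lobule CC
   meshwork, gamma speckle, rigid jitter, random-walk pachyvessel ribbons,
   cohort tables at the published group parameters), because the raw device
   images for this kind of study are not publicly deposited.

## Worked example

```r
library(ccflow)
scene   <- generate_scene(seed = 1)          # truth: 13% void fraction, ~790 um2 voids
stack   <- render_octa_stack(scene, acquisition_params(seed = 2))  # 9 frame pairs
choroid <- render_choroid_oct(scene, seed = 3)
eye     <- run_eye(stack, choroid)
eye
#> <eye_result> 9/9 frames averaged
#> <flow_void_metrics> 1477 voids, total 1.2283 mm^2, mean 831.6 um^2
#> <overlap_metrics> pachyvessel portion 19.89%, void over vessel 18.86%
```

The true void fraction of this scene is 0.130 (1.17 mm² over the 9 mm²
field); the pipeline measures 1.23 mm² through the full
register–average–threshold–label chain, and the void-over-vessel share
(18.9%) tracks the vessel area portion (19.9%) because the generator places
voids independently of vessels — the "flow deficit is not co-localized with
pachyvessels" configuration.

Group inference runs directly from published-style summaries:

```r
ttest_two_sample(summary_stat(32, 62.5, 8.6), summary_stat(30, 65.2, 9.9))
#> age: t = -1.148, df = 60, p = 0.255
ttest_two_sample(summary_stat(32, 1.16, 0.18), summary_stat(30, 0.91, 0.16))
#> total void area: t = 5.765, p = 3.02e-07
chisq_2x2(matrix(c(25, 18, 7, 12), 2))
#> sex ratio: chi2 = 2.393, p = 0.122
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study on synthetic data,
writing tables and images under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | draws the 32 + 30 eye cohort at the published group parameters |
| `02_image_pipeline.R`  | renders and analyzes every eye through the full image chain (`run_all()`); set `CCFLOW_EYES=10` for a quick pass |
| `03_group_tables.R`    | builds the three group-comparison tables with unadjusted and age/sex-adjusted p-values |
| `04_pachyvessel_overlap.R` | co-localization: overlap share vs vessel portion, plus its (null) correlations with age and the void metrics |

Configuration is a single JSON/YAML file (see `load_config()` /
`default_config()`); every run is a pure function of its seed, and
`run_all()` emits a content-hash manifest that is byte-identical across
reruns.

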