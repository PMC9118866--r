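---
title: "Estimating wheat LAI from multi-sensor UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating wheat LAI from multi-sensor UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavlai)
```

## The problem

Leaf area index (LAI, half the total leaf area per unit ground area,
m²/m²) is the workhorse descriptor of crop canopy development. Modern UAV
platforms carry a multispectral camera, a long-wave thermal sensor and a
photogrammetric height product (digital surface model, DSM, and digital
elevation model, DEM) in a single co-registered stack at centimetre
resolution. At that resolution individual soil pixels are resolvable, which
raises two questions this package is built around:

1. Does removing the soil background before aggregating features to plot
   level improve LAI prediction?
2. Does fusing spectral, structural and thermal features beat any single
   sensor family?

The package implements the full analysis as testable units: a synthetic
scene generator with known ground truth, support-vector soil masking,
feature-raster extraction (15 vegetation indices, canopy height model,
normalized relative canopy temperature), plot-level zonal statistics, and a
model-comparison harness over random-forest (RFR), support-vector (SVR) and
multiple linear regression (MLR).

## The feature set

Per-pixel features are the five raw reflectance bands (B, G, R, RE, NIR),
fifteen band-arithmetic vegetation indices (NDVI, GNDVI, GRVI, NDRE, NDREI,
RVI, GCI, RECI, SCCCI, OSAVI with soil-adjustment constant L = 0.16, MCARI,
TCARI, their OSAVI ratios, and WDRVI with a = 0.12), the canopy height
model

$$\mathrm{CHM} = \mathrm{DSM} - \mathrm{DEM},$$

and the normalized relative canopy temperature

$$\mathrm{NRCT}_i = \frac{T_i - T_{\min}}{T_{\max} - T_{\min}},$$

with baselines taken over the whole field by default. Whether the NRCT
baselines should come from the whole field or from canopy pixels only is
genuinely ambiguous in practice; both are supported
(`nrct_extent = "whole_field"` or `"masked_canopy"`), with `whole_field`
the default because the baseline then does not depend on the mask quality.

**Undefined-value semantics.** Every cell whose formula divides by zero
(e.g. RVI at R = 0, or SCCCI where NDVI = 0) is flagged missing (`NA`),
never given a sentinel value: silent infinities would corrupt every zonal
mean downstream. Missingness commutes with masking (mask-then-compute
equals compute-then-mask; this is a tested property). Negative CHM cells —
photogrammetric noise can put the surface below the terrain — are clamped
to 0 and counted. Texture features are deliberately absent: no formula
defines them in the protocol this package follows.

## The synthetic scene generator

No field dataset ships with the package, so every downstream stage is
exercised on synthetic scenes with known truth. The generator emulates a
wheat trial of 80 plots of 2 m × 2 m (8 × 10 grid, 0.5 m bare-soil alleys)
imaged at 1.49 cm/pixel, with plot LAI drawn either uniformly or from a
piecewise-constant histogram concentrated at 1–3 with a secondary mode at
6–7 (the skewed distribution typical of a heading-stage trial; unreported
mid-range bins are filled uniformly and the bin table is configurable).

Generative links are the minimal monotone set that makes the qualitative
findings recoverable:

* **Cover.** A plot of LAI $L$ has target canopy cover
  $f = 1 - e^{-kL}$ (Beer–Lambert, $k = 0.5$), perturbed per plot on the
  logit scale with SD `cover_logit_sd = 0.6`. The perturbation models
  stand-density/emergence variation: real canopies with equal LAI differ in
  ground cover, which is precisely why exposed soil is contamination rather
  than a usable signal. With a deterministic cover link the retained-soil
  tables would *outperform* masked ones — the mixture fraction would be a
  noise-free second channel for LAI — inverting the phenomenon the package
  exists to study. Setting `cover_logit_sd = 0` recovers the exactly
  calibrated Beer-law cover (used by the calibration tests).
* **Spatial pattern.** Canopy pixels are the top `round(f·n)` values of a
  box-blurred Gaussian field (window `clump_scale_px = 15` px), giving
  spatially coherent patches rather than i.i.d. speckle, so masking is a
  non-trivial classification problem.
* **Reflectance.** Canopy reflectance per band is `base + slope·L` (NIR
  increasing, red/blue decreasing in L) plus a per-plot deviation
  (SD 0.015) and per-pixel noise (SD 0.01). Soil is bright
  (0.16–0.30 across bands) with a per-plot multiplicative brightness factor
  (SD 0.15) emulating moisture/colour patches. Values are clipped to [0, 1]
  with a logged count.
* **Height.** Canopy height is `0.55 m + 0.035 m·L` plus per-plot
  (SD 0.03 m) and per-pixel (SD 0.02 m) noise; DSM = DEM on soil.
* **Temperature.** Soil sits at 32 °C with per-plot patches (SD 1.5 °C);
  canopy runs cooler by 0.8 °C per unit LAI (transpiration), with per-plot
  (SD 0.5 °C) and per-pixel (SD 0.3 °C) noise.

All magnitudes are plausible for a heading-stage wheat canopy on bright
soil and were fixed once at design time. A single master seed fans out to
deterministic per-stage sub-seeds, so every scene is bit-reproducible.

What the generator does **not** emulate: radiative-transfer effects
(mixed-pixel spectra at canopy edges, multiple scattering between soil and
leaves, shadows), weeds, multi-date phenology, georeferencing error, or
photogrammetric artefacts beyond white noise. Passing tests therefore show
that the pipeline's logic is correct and that its conclusions hold under
this generative model — not that the specific accuracies transfer to any
real field.

## Soil masking

A linear-kernel SVM (`C = 1`) is trained on the five-band reflectance of
500 labelled pixels per class and applied to every pixel. Training and
held-out evaluation pixels are disjoint; accuracy is reported as a 2 × 2
confusion matrix with overall accuracy and Cohen's kappa (kappa is
explicitly signalled as undefined when the chance agreement is 1). The
classifier's input bands and the training sizes are configurable since no
single convention dominates in practice.

## Plot aggregation and modelling

Zonal statistics use pixel-center-in-polygon membership — the common
default, and exactly testable — and the mean over defined pixels; plots
with fewer than `min_pixels = 10` defined pixels are dropped with a log
message. The modelling table has one row per plot: 22 features plus
measured LAI.

`lai_fit()` is the modelling front-end. Methods:

* **RFR** — 100 trees (accuracy plateaus near there for tables of this
  shape); other forest hyperparameters at package defaults; seeded.
* **SVR** — linear kernel, `C = 1`, `epsilon = 0.1`, predictors
  standardized with *training* statistics only.
* **MLR** — ordinary least squares; a rank-deficient design falls back to
  the smallest-norm (pseudoinverse) solution with a warning.

Validation uses a random 70/30 plot split (`round(0.7·n)` training rows)
and reports $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (negative values allowed)
and RMSE. `run_combination_experiment()` crosses mask condition × method ×
feature set (Sp, Sp+Th, Sp+St, Sp+St+Th) under **one shared split**, so
feature-set effects are not confounded with split noise; the design was
open here, and sharing the split is the lower-variance choice.

Variable importance is the normalized mean impurity decrease for RFR. For
SVR no standard importance exists; the package defines the absolute
coefficient on the standardized predictor (equivalently |raw coefficient| ×
training SD), normalized to sum to 1 — transparent and testable, but a
documented divergence from proprietary workbench scores, so SVR rankings
are not expected to match other software. Ties break by feature-name
order. `common_top_k()` intersects the two top-10 lists (ordered by mean
rank) and a four-variable MLR is refit on the intersection;
`published_lai_model()` additionally ships the fixed published equation

$$\hat y = -390.65\,x_B - 12.14\,x_{NDRE} - 3.2\,x_{NRCT} + 9.49\,x_{CHM} + 12.92$$

for per-pixel prediction maps (`prediction_map()`; soil pixels are
nodata). For linear models the map commutes with aggregation: the zonal
mean of per-pixel predictions equals the prediction at zonal-mean features
on fully defined plots (tested to 1e-9).

## Numerical and interface choices

* Rasters are plain numeric matrices (row 1 = north); `NA` is the only
  missing-value representation.
* On-disk scenes use multi-page TIFF plus a JSON sidecar carrying the
  geotransform, CRS note and per-layer scale/offset (16-bit quantization;
  round-trip error is bounded by range/65535). Plot polygons are GeoJSON.
* Block-mean resampling (`resample_block_mean()`) degrades resolution by
  integer factors for resolution-sensitivity studies (e.g. 1.49 → 5
  cm/pixel at factor 3 or 4), averaging defined cells only.
* Determinism: a single master seed; sub-seeds are derived by hashing a
  stage label, all below 2³¹.

## Problem sizes used in the test-suite and acceptance runs

Replicated model-comparison runs use the full 80-plot design at 5 cm/pixel
(about 2.1 × 10⁵ pixels per scene, 20 scene replicates), which keeps
held-out sets at 24 plots — the same validation size as the 80-plot field
design. Masking accuracy is assessed at the native 1.49 cm/pixel scene
(about 2.4 × 10⁶ pixels). Single-purpose unit tests use 2–3 plot toy
scenes. These sizes are the package's reference conditions and are stated
here so results are interpretable; they are not tuning knobs.

## Known limitations

* Synthetic reflectance is linear in LAI per band; saturation of optical
  signals in dense canopies is represented only through the Beer-law cover
  term, so the advantage of structural features in very dense stands is
  likely understated.
* The SVM mask on synthetic scenes is near-perfect because class spectra
  are well separated; real scenes with shadows and mixed pixels will be
  harder, and the accuracy numbers here are a floor-check of the machinery,
  not a field claim.
* Ratio-form indices (RVI, GCI, RECI, MCARI/OSAVI, …) are heavy-tailed on
  noisy high-resolution imagery: a canopy pixel whose red reflectance is
  near zero can dominate a plot mean. Tree ensembles shrug this off;
  linear SVR occasionally extrapolates badly on such plots, which is
  visible as rare large negative test R² values. The package reports these
  honestly rather than winsorising features.
* MLR importance is intentionally undefined (error) rather than improvised.
* Single-date analysis only; no phenology.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  scene = scene_config(n_plot_rows = 4, n_plot_cols = 5,
                       pixel_size_m = 0.05, seed = 1),
  seed = 42)
res <- run_pipeline(cfg, out_dir = tempfile("uavlai"))
res$accuracy          # mask OA / kappa
res$experiment        # 16-cell comparison table
res$common_variables  # intersection of the two top-10 rankings
print(res$mlr)        # refit four-variable linear model
```
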