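---
title: "Methods: pixel-scale SOC mapping from laboratory hyperspectral images"
author: "socmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-scale SOC mapping from laboratory hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socmap)
```

## The problem

Subsoil organic carbon is low in content and strongly heterogeneous, so
classical sampling — cutting a core into a handful of depth increments and
homogenising each — averages away exactly the structure (biopores, root
channels, coldspots) that matters for understanding where carbon is
stored. Laboratory VNIR hyperspectral imaging of a sliced core face
records a full reflectance spectrum (here 186 bands, 400–990 nm) at every
pixel, down to ~53 × 53 µm. Because soil spectra darken with increasing
organic carbon, a regression calibrated on a modest number of
laboratory-analysed regions of interest (ROIs) can be applied to every
pixel, turning one core scan into millions of SOC predictions.

`socmap` implements that workflow end to end and pairs it with a
synthetic-core generator, so that every stage — normalization, masking,
SNV, calibration, regression, constraint and bias correction, bulk
evaluation, depth profiles, hotspot detection — is testable against known
ground truth without the original samples.

## Processing model

**Reflectance normalization.** Recorded intensity is converted to
reflectance against a reference scan of a calibration target of defined
reflectance (~50 %), per wavelength $\lambda$ and pixel column $x$:

$$R_{sample,\lambda,x} = \frac{I_{sample,\lambda,x}}{I_{target,\lambda,x}}
\cdot R_{target,\lambda,defined}$$

Dividing column-wise cancels horizontal illumination differences exactly;
the package verifies this as an identity on the synthetic forward model.

**Masking.** Non-soil pixels are removed with two rules on the normalized
cube: a minimum reflectance at the band nearest 980 nm (cracks,
macropores, shadows and stage background are dark in the NIR) and an
acceptance interval for the 980/420 band ratio (holder/background
material is spectrally flat, soil is not). The defaults
(`upperBandThreshold = 0.15`, `ratioBounds = c(1.5, 12)`) were calibrated
once against the synthetic generator's clean-soil distribution: they mask
no clean soil while recovering planted non-soil features with ≥ 99 %
pixel agreement. Masking only ever updates the mask, never the spectra.

**SNV.** The standard normal variate transform z-scores each pixel
spectrum over its bands (sample, $n-1$ denominator — fixed here so tests
are exact). SNV removes per-pixel multiplicative and additive scatter by
construction: `snv(a*s + b) == snv(s)` for `a > 0`. Pixels with a flat
spectrum cannot be transformed; they are masked and counted rather than
divided by zero.

**Calibration design.** Each ROI contributes spectra summarised twelve
ways (mean and median of the full region and of five random 1 % pixel
subsets, drawn independently without replacement; subset size
`max(1, roundHalfUp(0.01 n))`). Models train on three randomly chosen
subset spectra per ROI; the full-region spectrum and the remaining two
subsets validate. Mean spectra are the default for prediction. The
calibration limits are the range of measured ROI SOC.

**Regression.** Three algorithms, each behind the same interface:

* *PLS* — NIPALS with a single response, mean-centred unscaled
  predictors, written in-package. The component count is chosen by 5-fold
  cross-validated MSEP (ties to the smaller count); a forced count is
  also accepted, and the CV-optimal count is always reported.
* *Random forest* — `randomForest` with 200 trees, each grown on a random
  33 % draw of the training samples *without* replacement (so 67 % are
  genuinely out-of-bag; a classical bootstrap would leave only ~37 %
  out), `mtry = round(sqrt(bands)) = 14` for 186 bands, terminal node
  size 1. `randomForest` exposes no separate minimum-split parameter;
  node size 1 implies any node with ≥ 2 cases may split, which realises
  the intended settings.
* *SVM* — `e1071` ε-regression with radial kernel on predictors scaled
  per band to [0, 1] using stored calibration min/max (prediction spectra
  may legitimately fall outside [0, 1]; no clipping). The γ/C/ε grid
  (default γ ∈ 10^-3..1, C ∈ 1..32, ε ∈ {0.05, 0.1, 0.2}) is scored both
  by 10-fold CV RMSE and by bootstrap RMSE (train on a random third,
  evaluate on the rest); CV decides. ε applies to the unscaled response
  (mg g⁻¹). If ε exceeds every residual the dual problem has no support
  vectors; the fit then degenerates, correctly, to the constant mean
  predictor.

**Constraint and bias correction.** PLS extrapolates linearly into
spectra outside its calibration range and produces implausible values;
the constraint operator replaces negatives with the calibration minimum
and values above the calibration maximum with the maximum — values in
`[0, socMin)` are deliberately left alone, and the operator is
idempotent. Tree ensembles instead regress toward the node mean:
carbon-rich topsoil is underestimated and carbon-poor subsoil
overestimated. The depth-stratified bias correction estimates one
additive offset per horizon as the negated mean validation residual and
shifts map rows above/below the horizon boundary accordingly, with no
clipping afterwards (the corrected map may extend slightly past the
calibration limits). The residual correlation with horizontal position is
reported as a diagnostic; position across the core carries no information
about bias, so it should sit near zero.

**Evaluation.** ME, RMSE, MAE, RPD = sd(measured)/RMSE and
R² = 1 − SSE/SStot. The sd in RPD uses the population ($n$) denominator,
which makes R² = 1 − RPD⁻² an exact identity — the convention under which
published (RPD, R²) pairs such as (0.91, −0.21) and (2.31, 0.81) are
internally consistent. ME is signed as predicted − measured. Bulk
evaluation extracts the predicted map statistic (mean or median) over
each bulk-sample depth slab and compares with the measured value; the
"± 1 sd" variants take as effective prediction the point of
[stat − sd, stat + sd] closest to the measurement, so a measurement
inside the envelope scores zero error. That projection reading is the
only one under which a predictor with enormous slab variance attains a
formally perfect envelope score — which is precisely why the envelope
variants must always be read next to the plain ones; the package computes
all four.

**Spatial analysis.** Depth profiles use equal-area windows (default 6 cm
tall × full 6 cm width): mean, sd, CV, adjusted Fisher–Pearson skew and
pixel count per window; the last partial window is reported with its true
count. Hotspots are operationalised as 8-connected regions of pixels
exceeding `enrichmentThreshold` (default 2) times a local background (the
median of a square neighbourhood), quantified against the median of an
annulus reaching `annulusRadiusCm` (default 1 cm, the "directly adjacent"
soil) out from the region boundary and excluding the region; the median
is robust to neighbouring hotspots. Coldspots are the mirror image. No
published numeric hotspot definition exists; this rule is this package's
operationalisation and every piece of it is configurable.

## The synthetic generator: what it emulates, and what not

`syntheticCoreConfig()` defaults encode the study conditions of a
cultivated loess profile:

| parameter | default | meaning |
|---|---|---|
| `coreHeight`, `coreWidth` | 100, 6 cm | 1 m core, 6 cm face |
| `pixelSize` | 2500 µm | 400 × 24 grid (see below) |
| `ploughDepth` | 30 cm | plough-horizon depth |
| `ploughMeanSOC`, `ploughCV` | 9 mg g⁻¹, 0.2 | homogeneous mixed topsoil |
| `subsoilSOCAtBottom` | 2 mg g⁻¹ | linear mean decline below 30 cm |
| `subsoilCVAtBottom` | 0.7 | linear CV rise with depth |
| `biopores` | 3 channels, enrichment 2.5 / 3 / 4 | vertically elongated subsoil hotspots |
| `socMeasurementSD` | 0.45 mg g⁻¹ | half the 0.9 mg g⁻¹ limit of determination of dry combustion |

The SOC field is Gaussian-smoothed white noise (~2 mm correlation length
— the variance structure is documented for these soils, the correlation
structure is not, so a short generic range was chosen) scaled to the
depth-dependent mean and CV. Biopores are rectangles with a one-pixel
linear edge taper (their delimitation in real cores is blurred); their
core SOC equals enrichment × the local matrix mean.

The forward optical model renders reflectance
$r(\lambda) = b(\lambda)\,e^{-k(\lambda)\,SOC}$ with $k$ larger in the
visible than the NIR — a smooth, monotone, *nonlinear* darkening, so that
linear and nonlinear regressors genuinely differ — and records intensity
$g(x)\,a\,r\,L(\lambda) + b_{px} + \varepsilon$ with a horizontal
illumination gradient $g$, per-pixel log-normal gain $a$ and additive
offset $b_{px}$, lamp spectrum $L$, and band noise. Noise scales
(additive offset sd 0.005, band noise sd 0.003, in units where typical
signal is 0.1–1) are a few percent of signal, as for a cooled pushbroom
VNIR camera; much larger additive noise would bury the 420 nm band of
dark pixels and make the published 980/420 masking rule physically
unusable, contradicting the phenomenon the generator emulates. Cracks are
rendered dark across all bands, holder columns spectrally flat.

What the generator does **not** emulate: mineralogy and moisture effects
on spectra (the baseline and $k(\lambda)$ are smooth low-order shapes,
not radiative transfer), 3D structure behind the cut face, inorganic
carbon chemistry (truth is organic carbon directly), topsoil root/residue
speckles (available but off by default, as no quantitative description
exists), and instrument artefacts beyond scatter/gradient/noise. Passing
tests therefore show the *pipeline* recovers what it assumes about real
data — not that real soils satisfy those assumptions.

## Numerical and design choices

* Coordinates: row 0 is the soil surface; depth_cm = depthOrigin +
  row × pixelSize; all depth intervals are half-open [top, bottom).
* Default grid 2500 µm/pixel (400 × 24). A literal 53 µm grid
  (1132 × 18868 px) is configurable but pointless for testing; 2.5 mm
  keeps mm-scale biopores ≥ 2 px wide and a 3 × 3 px ROI at 0.56 cm²,
  inside the physical ROI area range (0.1–4.8 cm²).
* PCA renderings are computed per core on normalized reflectance
  (mean-centred, unscaled); whether SNV input would be preferable is
  genuinely open, so the treatment is an argument. Loading signs are
  fixed by making each vector's largest-magnitude element positive.
* Ties in PLS component selection go to the smaller count; `which.min`
  makes this deterministic.
* The 3-of-5 train/validate subset split is seeded-random per ROI; the
  five 1 % subsets are drawn independently (not forced disjoint), and the
  seed is recorded.
* Bias offsets are reported at full precision; a display rounding to
  0.1 mg g⁻¹ is applied only in `show()`.
* One global seed drives every stage through labelled sub-streams
  (`substreamSeed`), so a fixed seed gives bit-identical cores, ROI
  draws, folds and forests, and adding a stage does not shift the
  others.
* Degenerate inputs fail loudly: zero/negative target intensity (with
  band and column identified), overlapping biopores, cutting schemes with
  gaps, all-masked cubes, constant-SOC calibrations; thresholds that mask
  100 % of pixels warn rather than silently emptying the map.

## Problem sizes in the test-suite

The packaged tests run the full chain — generator → preprocessing → ROIs
→ PLS/RF/SVM → maps → constraint/bias correction → bulk evaluation →
profiles and hotspot recovery — on single cores at the default 400 × 24
grid across ten seeds, with 30 ROIs per core and the SVM fixed at its
published operating point (γ = 0.01, C = 8, ε = 0.1) inside the recovery
loops; the orchestration smoke test uses two cores at a 200 × 12 grid
with the full five-map × two-treatment output set. These sizes were
chosen so the whole suite completes in a few minutes while every
statistical claim is still made across ≥ 10 independent seeds.

## Known limitations

* The bias correction is a two-stratum additive shift; residual bias that
  varies continuously with depth (or with SOC itself, which is the
  underlying cause) is only partially removed.
* The hotspot detector's local-median background underestimates
  enrichment for regions wider than the annulus, and reports an undefined
  reference (flagged, not dropped) where the annulus is fully masked.
* RPD/R² are undefined for zero-variance measurements and are flagged,
  not imputed.
* The ENVI I/O supports band-sequential interleave with byte/float
  types — the subset the pipeline writes — not BIL/BIP variants.
* Envelope ("± 1 sd") evaluation scores are optimistic by construction;
  they are reported alongside, never instead of, the point scores.
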