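---
title: "Predicting plum soluble solids by fusing Vis/NIR spectra with fruit images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plum soluble solids by fusing Vis/NIR spectra with fruit images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumfuse)
```

## The problem

Soluble solid content (SSC, °Brix) is the standard refractometric measure of
fruit sweetness and a key grading criterion for plums. Visible/near-infrared
(Vis/NIR) reflectance over 400–1100 nm carries chemical information about
dissolved sugars; an RGB image of the same fruit carries color and texture
cues that correlate weakly with ripeness. plumfuse implements a complete
chemometrics pipeline that predicts SSC from each modality alone and from a
weighted fusion of the two, and evaluates all three models on a common
held-out partition.

The pipeline is: reflectance calibration → spectral preprocessing →
wavelength selection → visual feature extraction → Z-score standardization →
OLS-learned fusion weights → partial least squares regression (PLSR) →
evaluation by R², RMSE and RPD. Because no fruit dataset ships with the
package, a seeded synthetic generator reproduces the statistical structure
such an experiment assumes, so every stage is testable end to end.

## The synthetic data generator

The generator is first-class, tested code, not a fixture. It emulates a
free-fall acquisition of 120 plums:

* **SSC reference values** are drawn from a normal distribution with mean
  13.00 and SD 1.25 °Brix, truncated by rejection to [10.2, 15.3] °Brix.
  Rejection rather than clipping preserves the truncated-normal shape.
  Truncation at roughly ±2 parent SDs shrinks the *expected sample SD* of a
  cohort to about 1.10 °Brix; the sample mean is essentially unbiased.
* **Spectra.** Each fruit's true reflectance is a gentle quadratic baseline
  plus Gaussian peaks at 720 and 820 nm (FWHM ≈ 40 nm) whose amplitudes are
  affine in SSC, minus a narrow valley near 740 nm. Raw counts are
  `dark + (scatter · r + offset) · (white − dark) + noise`: calibration
  against the returned dark/white references recovers `r` exactly when all
  noise knobs are zero. Signal intensity scales with integration time
  (default 14 ms) and inversely with spot diameter (default 20 mm);
  per-wavelength noise SD scales with disc motor speed (default 6.6 r/min).
  These acquisition knobs are scalar signal/noise multipliers only — no
  optics are simulated, and the absolute intensity scale is arbitrary
  because detector units are not modelled.
* **Images** are 96×96 8-bit RGB renderings of an elliptical fruit on a dark
  background: a base plum color shifted by `coupling` (default
  (2.5, 1.0, 0.5) channel units per °Brix), a fixed low-frequency texture
  field, per-sample color jitter, and per-pixel grain.

Two design choices matter for what the downstream models can achieve.

**The vision ceiling.** The dominant per-sample color jitter acts *along the
SSC-coupling direction* in RGB space. Pooling more channels therefore cannot
beat the one-dimensional signal-to-noise ratio, and the attainable
image-only R² is `var(ssc) / (var(ssc) + σ²)` with σ the jitter expressed in
°Brix equivalents. The default `noise_sd = 3.2` channel units sets that
ceiling so an image-only model reaches R² ≈ 0.3–0.4 on held-out fruit —
the "weak but real" appearance signal the pipeline is designed around. An
additional isotropic jitter component (0.75 × `noise_sd`) adds general
color variability.

**The complementary matrix factor.** Each fruit also carries a standard
normal latent "matrix factor", drawn in its own named substream of the
global seed so that the spectra and image generators agree on it while
remaining independently reproducible. The factor perturbs the SSC value
*driving the spectrum* (scaled by `ssc_equivalent_noise_sd`, default
0.35 °Brix) — emulating un-assayed matrix effects such as skin or ripeness
stage that bound spectral accuracy — and simultaneously tints the fruit's
color along `matrix_coupling`, a direction independent of the SSC coupling.
Appearance thus carries a trace of exactly the variation the spectra
mis-read. This is what makes fusion *informative*: if the image block merely
repeated the spectral information with independent noise, the attainable
gain from fusing would be smaller than seed-to-seed evaluation noise (we
measured an ideal-stacking bound of under +0.02 R² in that regime), and no
fusion scheme could demonstrate anything. With the complementary design, a
fused model can partially cancel the spectral error term, which is the
qualitative behavior the pipeline exists to show. Per-wavelength detector
noise alone cannot play this bounding role, because PLSR averages it away
over ~700 channels.

## Preprocessing

Calibration computes `R(λ) = (S − D) / (W − D)` per sample and refuses any
wavelength where the white reference does not exceed the dark current. Five
treatments are available, specified as chain strings: `SG`, `SNV`, `MSC`,
`SG+SNV` (the default), `SG+MSC`.

* Savitzky–Golay defaults to window 11, order 2 — a conventional smoothing
  choice on a 1 nm grid; both are exposed in the configuration. Edges are
  handled by evaluating the boundary window's polynomial at the edge
  positions so the wavelength grid (which selection results index into)
  never shrinks.
* SNV standardizes each spectrum with the sample (n−1) SD — stated
  explicitly because the `[1, 2, 3] → [−1, 0, 1]` contract depends on the
  denominator.
* MSC regresses each spectrum on a reference and inverts the fitted affine
  map. With `reference = "mean"` the reference is the *training-set* mean,
  frozen in the fitted chain and replayed on test data, so no test
  information leaks into preprocessing.
* Zero-variance spectra raise errors naming the sample rather than being
  silently zeroed; degenerate inputs should be visible.

Modelling uses reflectance throughout; absorbance `log(1/R)` can be
emulated by transforming the calibrated table before `fit_preprocess()`,
but no claim is made that either choice matches any particular instrument
convention.

## Wavelength selection

Three selectors return a `selection_result` (indices, diagnostics trace,
seed); all are deterministic given their inputs and seed, and all are fitted
on the training partition only.

* **CARS** (competitive adaptive reweighted sampling), the pipeline default:
  50 Monte-Carlo runs, each fitting a PLSR on 80% of the calibration
  samples; variables are weighted by normalized absolute regression
  coefficients, cut to `⌈r_i · p⌉` by an exponential schedule pinned at
  `r_1 = 1` and `r_N = 2/p`, then resampled with probability proportional to
  weight. Each run's set is scored by 5-fold RMSECV; the best run wins, with
  ties broken toward fewer variables and then the earlier run (parsimony and
  determinism). Run count, fraction and folds follow the common usage of the
  algorithm; none are sacred and all are arguments.
* **SPA** (successive projections algorithm) grows chains of maximally
  orthogonal columns from every start and scores each (start, length) chain
  by held-out least-squares RMSE on a seeded 80/20 split — the standard
  formulation when no explicit scoring rule is prescribed.
* **UVE** (uninformative variable elimination) appends `p` artificial noise
  columns, refits a PLSR per leave-one-out fold, and computes per-variable
  reliabilities `mean(b)/sd(b)` across folds; real variables must beat the
  99th percentile of the noise reliabilities (a percentile rather than the
  maximum resists a single extreme noise value). The internal PLSR
  autoscales columns per fold, which makes reliability scale-free — without
  autoscaling, rescaling a column would change its reliability because PLS
  is not scale-equivariant — and makes the nominal `noise_scale` (1e−10)
  irrelevant in magnitude.

Selected-variable counts are data-dependent diagnostics, not contracts.

## Visual features

Each image yields a frozen, versioned 16-vector: mean and SD of R, G, B;
mean and SD of CIELAB L*, a*, b* (sRGB → Lab under D65/2°); and four
gray-level co-occurrence matrix textures — contrast, dissimilarity, energy,
homogeneity — each averaged over the four orientations 0°, 45°, 90°, 135°
at a one-pixel offset. Pixel statistics use the population (n) SD: the
pixels *are* the population of the imaged region. GLCM matrices are made
symmetric and normalized before property computation, and energy is the
angular second moment ΣP² (not its square root, which some libraries report
under the same name). Luminance uses ITU-R BT.601 weights quantized to 32
levels over the fixed [0, 255] range — 32 levels keeps the co-occurrence
matrix well populated for small fruit regions. An optional fruit mask
(e.g. from thresholding) restricts the color statistics, with GLCM computed
on the mask's bounding box; masking is off by default. One upstream
description of this feature block calls it 15-dimensional; the package
implements the enumerated 12 + 4 = 16 layout consistently.

## Modelling and fusion

Samples are split 7:3 by a seeded shuffle. PLSR is a single-response NIPALS:
weights `w ∝ X'y`, scores `t = Xw`, deflation by `t p'`; with one response
each component is an exact one-step solution, and with `n_latent = p` on
full-rank tall data the fit reproduces OLS. The latent-variable count is
chosen by 5-fold cross-validation (shuffle seed 42 by default, upper bound
25), exploiting that NIPALS models are nested so one fit per fold scores
every candidate count; ties go to the smallest count.

For fusion, each block is Z-scored with training-set statistics, then an
ordinary least squares fit of the response learns the weights. The default
`per_feature` mode regresses on the concatenated blocks and uses the
absolute per-feature coefficients (a sign only flips a standardized feature,
which PLSR absorbs; absolute values keep the emphasis reading); when the
design is rank-deficient — common when selection retains more wavelengths
than training samples — the minimum-norm least-squares solution is used with
a warning. The `per_block` mode regresses the response on the two
within-block PLSR prediction vectors and broadcasts the two absolute scalars
across their blocks. Weighted blocks are concatenated, spectral first, and
refitted by PLSR.

Evaluation reports R², RMSE per partition and, for the test partition,
RPD = SD(y_test)/RMSE with the (n−1) SD — the dominant chemometrics
convention, since no single formula is universal. A zero test RMSE reports
RPD as `Inf` rather than failing.

No fitted object — preprocessing state, selection, standardizers, fusion
weights, latent counts — depends on the test partition; the test suite
asserts this by scrambling the held-out samples' raw data and checking all
fitted objects are bit-identical.

## A full run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(n_samples = 120, seed = 1)
res <- run_pipeline(cfg)
res
autoplot(res)
```

With the default conditions (120 fruits, SG+SNV, CARS, per-feature fusion)
the three test-set R² values over seeds 1–10 have medians of about 0.86
(spectral-only), 0.37 (image-only) and 0.93 (fused): fused ≥ spectral ≥
image, the ordering the pipeline is designed to exhibit. These numbers are
properties of the synthetic generator's settings, not predictions for any
physical instrument.

## Numerical choices and degenerate inputs

* All randomness flows from one integer seed through named substreams
  (`ssc`, `spectra`, `images`, `matrix`, `cars`, `spa`, `uve`, `split`), so
  regenerating one stage never perturbs another.
* The CARS schedule endpoints are pinned exactly (`r_1 = 1`, `r_N = 2/p`)
  and the retained count computation guards the boundary products against
  upward floating-point rounding.
* NIPALS stops early if the residual covariance norm falls below 1e−12
  (exactly collinear or exhausted data); a model with zero extractable
  components is an error, as are zero-variance responses and features.
* MSC slopes below 1e−12 in absolute value are errors naming the sample.
* Empty SSC tables generate empty spectra sets (not errors); empty
  partitions from extreme split ratios are errors.

## What the synthetic tests do and do not show

Passing the suite demonstrates that every algorithmic contract holds and
that the pipeline's qualitative behavior — scatter-correction invariance,
selection recovering planted bands, the fused ≥ spectral ≥ image ordering,
exact recovery as noise vanishes — emerges from data with the assumed
structure. It does not show that any particular accuracy is attainable on
real fruit: real spectra have instrument line shapes, stray light,
temperature drift and nonlinear scattering that the affine forward model
omits; real fruit images have specular highlights, pose variation and
camera effects the renderer omits; and the complementary matrix factor is
an idealization of how appearance relates to spectral confounds. Problem
sizes in the tests (cohorts of 40–120 fruits, grids of 181–701 wavelengths)
were chosen as representative desk-scale instances of the study design.

## Limitations

* Single response only; no multi-response PLS.
* No derivative/detrending/OSC preprocessing and no other selectors (GA,
  iPLS) — the implemented five treatments and three selectors span the
  comparison the pipeline targets.
* Linear models throughout; no SVR or neural baselines.
* The image pipeline extracts color and GLCM features only — no shape, size
  or learned features.
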