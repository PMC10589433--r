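---
title: "Estimating BOLD-CVR and relating it to small vessel disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating BOLD-CVR and relating it to small vessel disease: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrsvd)
```

## The measurement problem

Cerebrovascular reactivity (CVR) quantifies how much cerebral blood vessels
dilate in response to a vasodilatory stimulus. In a gas-challenge fMRI
experiment the subject alternately breathes medical air and CO2-enriched
air (6% CO2 here, 2-minute air and 3-minute CO2 blocks over a 12-minute
scan), end-tidal CO2 (EtCO2, mmHg) is recorded breath by breath as a proxy
for arterial CO2, and the BOLD signal is acquired continuously
(TR 1.55 s). CVR is reported as the percent BOLD signal change per mmHg
change in EtCO2 (%/mmHg).

In small vessel disease (SVD) the quantity of interest is tissue-level CVR
in subcortical grey matter (SGM), normal-appearing white matter (NAWM) and
white matter hyperintensities (WMH). Voxel-wise estimates in these tissues
are noise-dominated, so the pipeline estimates CVR from the *mean* BOLD
series of each region.

## The CVR model

For one region, let $S_k$ be the mean BOLD signal of volume
$k = 0, \dots, n-1$ and $y_k = 100\,(S_k - \bar S)/\bar S$ its percent
change about the temporal mean. With $x_k(\delta)$ the EtCO2 regressor
evaluated at the volume timestamp minus a candidate delay $\delta$, the
model at each delay is ordinary least squares:

$$ y_k = \beta_0 + \beta_1\, x_k(\delta) + \beta_2\, k + \varepsilon_k $$

where the volume-index term absorbs linear scanner drift. The hemodynamic
delay is chosen per subject and region as the grid value minimizing the sum
of squared residuals (SSR), and $\hat\beta_1$ at that delay is the CVR in
%/mmHg. Delay ties (identical SSR to within a relative $10^{-9}$) are
broken towards the smallest $|\delta|$, then the smaller $\delta$ — in
practice ties only arise in degenerate inputs.

Choices that were genuinely open, and how they were fixed:

* **Normalization baseline.** "Percent change" needs a reference. An
  intercept-based baseline is confounded with the drift term, so the
  series' own temporal mean is used: $y$ has zero mean by construction,
  CVR is invariant to rescaling the raw signal, and the estimator is the
  exact inverse of the package's generative model (below). The
  alternative — fitting the raw signal and dividing the coefficient by
  the mean — is algebraically equivalent to second order.
* **Delay grid.** Default $-5$ to $+60$ s in 1 s steps. White-matter
  responses in SVD can lag the stimulus by tens of seconds; the small
  negative range lets genuinely acausal fits (usually noise) be detected
  rather than clamped at 0. The grid always contains 0, and every fit
  uses all $n$ volumes (constant-edge extension of the regressor), so SSR
  is comparable across delays.
* **Volume timestamps.** Mid-acquisition ($k\,\mathrm{TR} + \mathrm{TR}/2$)
  by default, configurable to volume-start; the choice shifts all delays
  by TR/2 and nothing else.
* **Drift units.** The fitted drift coefficient is % per volume index;
  results report `drift_pct_per_scan` $= n\hat\beta_2$, the total percent
  excursion over the scan.

A consequence of mean-referencing worth knowing: adding an *uncentered*
linear trend to the raw signal also moves the temporal mean and therefore
rescales all percent values by a common factor; invariance of CVR to drift
is exact for zero-mean trends and holds to first order otherwise.

## Mask conditioning

Region masks arrive in BOLD-registered space (segmentation and
registration are upstream of this package) and are conditioned in a fixed
order, recorded in a provenance list:

1. erode SGM and NAWM by 1 mm in all directions (partial-volume
   reduction);
2. dilate the ventricle mask by 5 mm left-right and 4 mm
   anterior-posterior and superior-inferior (large vessels run along the
   ventricles);
3. subtract the dilated ventricle mask from NAWM and WMH;
4. subtract an optional manually-derived large-vessel exclusion mask from
   all tissues.

WMH masks are not eroded: they are often only a few voxels, and only SGM
and NAWM erosion is part of the protocol. Structuring elements are
axis-aligned boxes — per-direction millimetre extents map directly onto
box half-widths — and mm-to-voxel conversion uses `ceiling`, so the stated
physical margin is always guaranteed. Anatomical axes are resolved from
orientation metadata (or an explicit `axes` argument); the morphology is
implemented as separable axis shifts, which is exact for box elements.

A WMH mask that empties after conditioning is not an error of the subject:
the region is skipped with a recorded reason and the remaining regions are
still analysed, mirroring how small WMH masks behave after registration at
BOLD resolution.

## The synthetic-data generator

Because the cohort data underlying the published analysis are not
deposited, every stage is validated against synthetic data whose ground
truth is set to the published summary values.

* **EtCO2 traces.** The underlying level follows
  $\mathrm{baseline} + \Delta \cdot \mathbb{1}_{\mathrm{CO2}}(t)$ smoothed
  by a first-order exponential (default $\tau = 15$ s), the simplest
  physiologically plausible block response, sampled at breath times
  (default 4 s intervals with 0.4 s Gaussian jitter — realistic resting
  respiration, and it forces the resampling logic to do real work).
  Defaults: baseline 38 mmHg, $\Delta = 8$ mmHg under 6% CO2.
* **BOLD series.**
  $S_k = S_0\,(1 + \frac{c}{100}(x_k - \bar x) + \frac{d}{100}\frac{k - \bar k}{n}) + \varepsilon_k$,
  with $x_k$ the trace at the volume time minus the true delay. The CO2
  and drift components are mean-centred so that $S_0$ *is* the temporal
  mean of the noiseless series and $c$ is exactly the percent-of-mean
  change per mmHg. This makes the generator the exact inverse of the
  estimator: noiseless series with a grid-aligned delay are recovered to
  machine precision, which is the package's primary correctness oracle.
* **Phantom masks.** A nested geometry (ellipsoidal brain, ventricle
  slab, SGM blobs, NAWM shell, WMH caps face-adjacent to the ventricles)
  guarantees that every conditioning step, including the
  ventricle-dilation subtraction, operates on non-trivial input. Masks
  are pairwise disjoint by construction.
* **Cohorts.** Covariates and SVD features are drawn from families chosen
  once to approximate the published population summaries: normals for
  age/MAP/brain volume, log-normals for WMH and PVS volumes (so
  $\log_{10}$ WMH volume is the linear predictor), categorical scores
  with probabilities matched to the printed medians and IQRs, an
  overdispersed count for lacunes and a zero-inflated count for
  microbleeds. CVR per region is
  $\mathrm{intercept} + \sum_j B_j x_j + \varepsilon$ with configurable
  true coefficients; region intercepts default to the published medians
  (0.171, 0.042, 0.040 %/mmHg for SGM/NAWM/WMH).

What the generator deliberately does **not** emulate: spatially
structured fMRI noise, motion, registration error, physiological
confounds (respiration-rate or cardiac effects) and measurement error in
the SVD feature ratings. Passing recovery tests therefore demonstrates
the *estimators* are correct and calibrated, not that real acquisitions
meet the model assumptions.

## Calibrating recovery studies to printed precision

Coefficient-recovery simulations are only meaningful if the simulated
noise matches the precision of the published estimates. For an OLS
coefficient, $\mathrm{Var}(\hat B_j) = \sigma^2 / \mathrm{RSS}(x_j \mid Z)$,
where the denominator is the residual sum of squares of the predictor
regressed on the other model terms. A printed 95% CI is converted to a
target standard error via the $t$ quantile at the model's residual
degrees of freedom ($n - 10$ for the adjusted models at $n = 182$), and
the residual SD is back-solved per realised design:
$\sigma = \mathrm{SE}\cdot\sqrt{\mathrm{RSS}(x_j \mid Z)}$. The same logic
calibrates the paired inter-region contrast: the printed CI half-width of
the mean difference gives the SD of within-subject differences directly
($\mathrm{SD} = \mathrm{SE}\sqrt{n}$). Because the per-region residuals
in the simulator are otherwise independent, a target difference SD is
split as $\mathrm{SD}/\sqrt 2$ per region when both margins matter.

With this calibration the recovery studies check two things at once: the
replicate-averaged estimate matches the generating value (unbiasedness)
and the 95% CI covers it at the nominal rate.

## Cohort statistics

The cohort stage mirrors standard epidemiological practice: one OLS model
per (region, predictor) pair, univariable or adjusted for age, sex, mean
arterial pressure, smoking history (never / ex-smoker > 1 year /
current-recent, never as reference) and diagnoses of hypertension,
diabetes and hypercholesterolaemia. Conventions:

* complete-case analysis per model, with `n_used` reported;
* WMH volume enters as $\log_{10}$(%ICV); non-positive volumes (absent in
  realistic cohorts, since volumes are drawn log-normal) are excluded
  with a warning rather than offset;
* 95% CIs from the $t$ distribution with residual degrees of freedom;
* collinearity screened via the condition number of the scaled design
  (warning above 30, a common heuristic);
* residual diagnostics (Shapiro-Wilk, Breusch-Pagan) are advisory flags
  at $\alpha = 0.05$, never automatic refits;
* no multiple-comparison correction — estimates and intervals are
  reported rather than significance decisions;
* standardized coefficients default to the both-variable z-score
  convention $B\,\mathrm{sd}(x)/\mathrm{sd}(y)$ (a predictor-only
  convention is available), computed on each model's complete cases.

The full adjusted table is one model per predictor row (20 rows: WMH
volume, three Fazekas scores, lacunes, microbleeds, three atrophy scores,
brain volume, six PVS measures, SVD score, NIHSS, mRS, MoCA) by three
regions.

## Numerical choices and degenerate inputs

* A constant EtCO2 regressor (e.g. an all-air paradigm) is a degenerate
  design and raises a typed error; in the per-subject driver this skips
  the region with a logged reason.
* A non-positive temporal mean of the BOLD series is a signal error
  (percent change undefined).
* Empty masks are allowed as morphology *outputs* (erosion may empty a
  mask) but are errors at extraction time.
* Exact-fit residuals (SD below machine tolerance) make the assumption
  checks report "unavailable" rather than returning meaningless p-values.
* Cohort draws with a constant covariate (possible at small n) warn and
  regenerate with the next seed, at most five times.

## Problem sizes

The test-suite and acceptance runs use desk-scale problems chosen to keep
the full suite under a minute while leaving no stage untested: 12-minute
paradigms at TR 1.55 s (464 volumes) for single-subject recovery, 80-volume
series for fitting properties, $24^3$–$32^3$ phantoms at 2.5 mm for the
imaging chain, cohorts of n = 182 (the published analysis size) with
200–500 replicates for coefficient recovery and coverage. Monte-Carlo
standard errors at these sizes are a few percent of the quantities checked.

## Known limitations

* Per-region residuals in the cohort simulator are independent across
  regions; real inter-region CVR correlations are higher. Only the paired
  contrast calibration accounts for this explicitly.
* The delay grid search is exhaustive rather than interpolated; delays are
  only resolved to the grid step (1 s default).
* Temporal realignment, registration and segmentation are consumed as
  inputs, not estimated; the input contract assumes motion-corrected BOLD.
* CVR delay itself is estimated but not analysed further (limited
  repeatability at these noise levels); cortical grey matter is out of
  scope (cortical thinning and surface vessels contaminate the signal).
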