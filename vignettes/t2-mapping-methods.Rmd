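---
title: "Myocardial T2 mapping: models, conventions and design choices"
author: "myoT2map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myocardial T2 mapping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoT2map)
```

## The measurement model

Transverse magnetization after excitation decays monoexponentially, so
the magnitude signal of a tissue pixel across a multi-echo train is

$$S(\mathrm{TE}) = h\,e^{-\mathrm{TE}/T_2} + y_0,$$

with amplitude $h$, relaxation time $T_2$ (ms) and a constant offset
$y_0$. The offset is not part of the physics: magnitude reconstruction
of complex data with independent Gaussian channel noise of SD $\sigma$
yields Rician-distributed intensities, whose mean approaches
$\sigma\sqrt{\pi/2}$ as the true signal approaches zero. That residual
"noise floor" is what $y_0$ models.

Treating $y_0$ as known and constant linearizes the problem:
$\ln(S - y_0)$ is linear in TE with slope $-1/T_2$ and intercept
$\ln h$. `fitPixelLinearized()` / `computeT2Map()` implement exactly
this: subtract the bias, drop echoes whose intensity is at or below it
(the log of a non-positive residual is undefined, and clipping would
bias the slope), and fit ordinary least squares. The coefficient of
determination of that regression is the goodness-of-fit filter: a pixel
is kept only when $R^2 \in [0.7, 1]$ *and* the slope is negative — the
interval alone would admit a well-fit rising series, which is
unphysical for decay data. Rejected pixels are missing values, never
zeros, in every downstream statistic.

`estimateBias()` pools the mean background magnitude over all echoes;
the default background region is four corner patches (8 px each side),
the standard artefact-free choice when no region is drawn, and both the
region and patch size are arguments. `fitPixelNLS()` is the
three-parameter Levenberg–Marquardt fit of the same model with $y_0$
free; it is the validation oracle the linearized path is tested
against, not the production path (per-pixel nonlinear fitting is two
orders of magnitude slower and needs convergence policing).

### Known bias of the constant-floor correction

Subtracting the full zero-signal floor $\sigma\sqrt{\pi/2}$
over-corrects pixels that still carry signal: for a Rician variable
with mean $\nu \gg \sigma$ the offset is only $\sigma^2/2\nu$. The
log-linear fit therefore underestimates $T_2$ by an amount that grows
with $\sigma$ and is slightly larger for shorter $T_2$. The test suite
characterizes this by Monte-Carlo (800 series, $h = 800$,
$T_2 = 60$ ms, 15 echoes of 10 ms): the median error is about
$-2.1$ ms at $\sigma = 5$, $-4.3$ ms at $\sigma = 10$ and $-13.6$ ms at
$\sigma = 40$, and the package fit reproduces an independent per-series
`lm()` simulation exactly. Consequences drawn throughout the package:

* absolute T2 values from the pipeline sit a few percent below the
  generating truth at realistic SNR — a property of the method, shared
  by any analysis that assumes an additive constant floor;
* contrasts (sex offsets, slice offsets, age slopes) are preserved up
  to a mild (~13% at $\sigma = 10$) inflation from the $T_2$-dependence
  of the bias, which is why pipeline-recovery checks compare effects at
  the between-subject standard error, where this distortion is small,
  rather than at the (far tighter) within-subject one.

## Rendering

`renderT2Map()` uses a spectral look-up table from black at the range
minimum (0 ms) through blue, green and yellow to red at the maximum
(150 ms by default); out-of-range values clamp to the ends, and
excluded pixels get a sentinel colour (white) that does not occur in
the table.

## AHA segmentation

Contours are closed polygons in displayed image coordinates (x = column
right, y = row down). `rasterizeMyocardium()` marks a pixel myocardial
iff its center lies inside the epicardial and outside the endocardial
polygon (even-odd rule); self-intersecting or non-nested contours are
rejected. `splitAhaSegments()` anchors sector 0 on the ray from the
myocardial centroid through the posterior right-ventricular insertion
landmark and sweeps clockwise on screen — the segmentation convention
used when maps are read slice by slice from the insertion point.
Mid-ventricular and basal slices get six 60° sectors, apical slices
four 90° sectors; bins are half-open `[start, start + width)` so no
boundary pixel is double-assigned. Sectors are numbered sequentially
from the anchor (basal 1–6, mid 7–12, apical 13–16; the apical cap,
segment 17, has no short-axis extent). The anterior-anchor,
counterclockwise textbook convention is reachable through the
`direction` argument and the landmark supplied. Angles are measured at
the mask centroid — contours make no promise of being concentric — and
every call asserts that the labels partition the mask exactly.

## Strain metrics

Circumferential strain (Ecc, %; negative = shortening) is consumed as
per-segment time series at a fixed 25 ms frame spacing. Peak systolic
strain is the global minimum. For peak diastolic strain — "the minimum
after early diastolic relaxation" — relaxation first has to be
detected: the package requires strain to regain a configurable
fraction (default 20%) of the systolic excursion after the global
minimum, takes early relaxation to end at the running maximum after
that onset, and returns the minimum from there on. On a monotone
recovery this is the final-frame value; a post-relaxation dip is picked
up as the diastolic peak; a series that never recovers yields a missing
value with a reason. The 20% threshold is a documented choice — any
small fraction separates genuine relaxation from frame noise, and the
onset frame is exposed for inspection.

The early diastolic strain rate is the least-squares slope of strain
versus time from end-systole to mid-diastole expressed per second —
identical to endpoints/Δt on a linear recovery and equal to Δstrain/Δt
for a two-frame window — reported as a positive magnitude (the signed
slope travels in an attribute). The acquisition-window rate is the mean
absolute frame-to-frame rate across the end-diastolic readout window.

## Observer agreement and cohort statistics

`observerAgreement()` returns the mean and SD of paired differences,
Bland–Altman limits at exactly $\pm 1.96$ SD, the Pearson correlation,
and the coefficient of variation = SD(differences) / mean of the
measurement × 100. The denominator is the grand mean of both observers
pooled: the definition does not say whose mean, and the pooled mean is
the symmetric choice. `pearsonRegression()` and `groupTTest()` delegate
to `cor.test()`, `lm()` and `t.test()`; the unpaired test defaults to
the pooled-variance Student form (a Welch option exists), and
essentially-constant inputs follow the $t = 0, p = 1$ convention with a
flag instead of erroring. p-values are kept at full precision; the 0.05
threshold appears only in summary flags. `waterFraction()` implements
the weighing rule (wet − dry)/wet with 0.63 — the fraction of fully
hydrated muscle — defining 100% tissue water.

## What the synthetic data emulate — and what they do not

The generators provide every input with known ground truth:

* **Phantoms** (`phantomSpec()`, `simulateEchoStack()`): an annular
  myocardium between concentric circles, blood pool inside, background
  outside, rendered as hard classes. Defaults: 64×64 grid, radii
  10/16 px (≈2 mm pixels), myocardial $T_2 = 60$ ms, $h = 800$,
  $\sigma = 10$ (first-echo SNR ≈ 80) — realistic 1.5 T mid-ventricular
  values chosen once; no measured phantom fixes them. Noise is Rician
  by construction (magnitude of a complex Gaussian perturbation).
  Per-sector $T_2$ tables let segmental contrasts be injected exactly.
* **Echo protocol**: 15 echoes at 10 ms spacing (150 ms train), the
  configuration that covers the complete myocardial decay.
* **Cohorts** (`cohortSpec()`): global $T_2$ additive-linear in age,
  sex and a subject residual, with slice offsets ordered
  apical ≥ mid ≥ basal (partial-volume thinning toward the apex raises
  apparent $T_2$) and an anteroseptal-vs-posterolateral contrast. The
  additive model is the simplest one consistent with the directions of
  effect it emulates. Defaults — intercept 51 ms, 0.17 ms/year,
  +4 ms for women, slice offsets (4, 2, 0) ms, residual SD 1.45 ms,
  40% women, ages uniform 20–80 — are calibrated so the generating
  age–$T_2$ correlation, with the sex offset counted as dilution, is
  0.77 at n = 70.
* **Strain curves**: piecewise linear (descend to the systolic peak,
  recover to a diastolic plateau, hold) plus frame noise — only the
  extrema and the recovery slope are analysed, so the shape carries
  exactly those features.
* **Drying series**: remaining water decays linearly to zero (default
  rate 0.05/h, fully dry at 20 h, so the 20–24 h rows form the dry
  plateau that anchors the 63% reference), and true $T_2$ tracks
  percent tissue water linearly with full-water $T_2$ = 60 ms.

Not emulated: k-space acquisition and reconstruction artefacts (EPI
ghosting, parallel-imaging noise amplification), partial-volume mixing
at tissue boundaries (slice offsets stand in for the apico-basal
partial-volume trend), cardiac or respiratory motion, and spatially
correlated noise. Passing tests therefore demonstrate correctness of
the estimation, segmentation and statistics layers under the stated
noise model — not robustness to acquisition artefacts in clinical
images.

## Numerical choices and degenerate inputs

* Echo samples at or below the bias are dropped, not clipped; fits need
  three surviving points, else the pixel is excluded with reason
  `"insufficient points"`.
* $R^2$ is clamped to $[0, 1]$ against floating-point overshoot so
  exact fits pass the closed upper tolerance bound; it is computed in
  the log domain, matching the linearized regression the filter is
  defined on.
* The nonlinear oracle runs `nls.lm` with an analytic Jacobian over a
  small ladder of starting points (data-driven, then two generic ones)
  and keeps the best converged deviance; zero-residual exact data are
  handled without spurious rank-deficiency failures.
* Angular bins are half-open and evaluated in double precision; the
  partition assertion runs on every segmentation call.
* Essentially-constant inputs to the t-test (relative SD below
  $10^{-10}$) take the degenerate conventions rather than erroring, so
  zero-noise simulated cohorts flow through the report.
* All generators accept a seed and restore the caller's RNG state;
  `NULL` draws from the current stream so one seed can drive a whole
  pipeline run.

## Problem sizes

The shipped tests run phantoms at 64×64 with 15 echoes, Monte-Carlo
characterizations at 800–10,000 series, and the full
simulate–fit–segment–report recovery at 70 subjects × 3 slices — sizes
at which every sampling check has comfortable power while a complete
suite run stays under a minute of CPU.

## Limitations

Absolute accuracy is bounded by the constant-floor bias discussed
above; the package reports it rather than correcting it, because the
correction (e.g. first-moment Rician modelling or power-image fitting)
would change the method under study. The DICOM pathway is a stub:
NIfTI volumes with JSON sidecars are the interchange format. Strain
series are consumed, not derived from tag-encoded images.
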