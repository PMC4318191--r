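# myoT2map

Quantitative myocardial T2 relaxometry from multi-echo short-axis
cardiac MR magnitude images, for imaging scientists who need a tested,
scriptable post-processing pipeline: pixel-wise T2 fitting with
noise-floor correction, AHA segmental statistics, strain-rate metrics,
observer-agreement and cohort statistics — plus a synthetic-data layer
that makes every stage testable against exact ground truth without any
scanner data.

## The model

Magnitude intensity of a pixel across an echo train decays as

S(TE) = h · exp(−TE / T2) + y0

where `h` is the amplitude, `T2` the transverse relaxation time (ms),
and `y0` the constant noise floor that Rician magnitude statistics put
under the decay (mean background magnitude σ√(π/2) for channel noise of
SD σ). The package estimates `y0` from background corner patches pooled
over all echoes, subtracts it, drops samples at or below the floor, and
fits ln(S − y0) against TE by ordinary least squares: `T2 = −1/slope`,
`h = exp(intercept)`. The log-domain R² is the quality filter — pixels
outside the tolerance interval [0.7, 1], or with a non-decaying slope,
are excluded as missing, never zero. A three-parameter nonlinear fit of
the same model (`fitPixelNLS()`) serves as the validation oracle.
Accepted pixels are summarised per AHA segment: 6 sectors of 60° on
basal/mid slices, 4 of 90° on apical ones, anchored at the posterior RV
insertion and swept clockwise.

Circumferential strain series (Ecc %, 25 ms frames) yield peak systolic
strain (global minimum), peak diastolic strain (minimum after early
relaxation), and the early diastolic strain rate — the end-systole to
mid-diastole slope in Ecc/s. Observer agreement is quantified by
Bland–Altman limits (±1.96 SD) and the coefficient of variation
(SD of paired differences / pooled mean × 100).

## Worked example

Simulate a mid-ventricular phantom with true myocardial T2 = 60 ms
under Rician noise (σ = 10), fit, segment, and summarise:

```r
library(myoT2map)

sim  <- simulateEchoStack(phantomSpec(myocardialT2 = 60),
                          echoProtocol(),          # 15 echoes x 10 ms
                          noiseSpec(sigma = 10, seed = 42))
mask <- rasterizeMyocardium(sim$geometry, c(64, 64))
map  <- computeT2Map(sim$stack, mask = mask)
map
#> T2Map: 64 x 64 pixels, bias y0 = 12.6, R^2 tolerance [0.7, 1]
#>   evaluated 496, accepted 496 (0.0% excluded)
#>   accepted T2: median 55.7 ms, range [48.0, 62.2] ms

seg <- segmentStatistics(map, splitAhaSegments(mask, sim$geometry))
seg
#>   segment nPixels nExcluded meanT2 medianT2  sdT2
#> 1       7      83         0  55.72    55.89 1.884
#> 2       8      83         0  55.46    55.22 1.937
#> 3       9      82         0  55.64    55.90 2.099
#> 4      10      83         0  56.15    56.33 2.364
#> 5      11      83         0  55.53    55.32 2.015
#> 6      12      82         0  55.81    55.94 2.246
```

The estimated bias (12.6) reproduces the theoretical floor
10·√(π/2) ≈ 12.5. Every myocardial pixel passes the R² filter, and the
six mid-ventricular segments (AHA 7–12) agree within their pixel SD.
The ~4 ms shortfall against the generating 60 ms is the documented
noise-floor bias of the constant-offset method at this σ — constant
across segments, so contrasts are preserved (see the methods vignette,
`vignettes/t2-mapping-methods.Rmd`).

Strain metrics from a synthetic curve
(`peakSystolicStrain`, `earlyDiastolicStrainRate`) return −20.1 % and
98.9 Ecc/s for the default curve at seed 42.

A cohort goes through the whole pipeline in one call:

```r
co  <- simulateCohort(cohortSpec(nSubjects = 70, seed = 1))
res <- runCohortPipeline(co, sigma = 10, seed = 1)
res$report$ageRegression   # Pearson R, slope, p of age vs global T2
```

A thin CLI wraps the same functions
(`inst/exec/myot2 simulate-phantom|simulate-cohort|fit|segment|strain|agreement|report`);
`fit --oracle` switches to the nonlinear reference fit.

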