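---
title: "Estimating in-season optimum nitrogen rates from satellite vegetation indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating in-season optimum nitrogen rates from satellite vegetation indices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aonrvi)
```

## The problem

Corn growers who sidedress nitrogen need to know, during the vegetative
window, how much N the crop will still respond to. The yield-based
answer -- the agronomic optimum nitrogen rate (AONR), the rate at which
a yield-versus-N response curve reaches its plateau -- is only available
after harvest. Vegetation indices (VIs) computed from 3-m satellite
surface-reflectance imagery are a candidate in-season proxy: if the
VI-versus-N response of a calibration strip saturates at the same rate
as yield does, the VI-based optimum (AONRvi) can stand in for the
yield-based one (AONRy) while there is still time to act.

`aonrvi` implements that analysis as a reusable pipeline for
strip-trial designs: transects of adjacent subplots spanning 4-5 N
rates (expressed as percentages of the farmer's normal rate), imaged at
up to seven growth-stage timings, with yields from combine yield
monitors. Because raw trial data of this kind are rarely shareable, the
package also ships a synthetic field-trial generator that reproduces
the statistical structure the analysis assumes, so every stage is
testable end to end.

## Pipeline stages

1. **Scene handling and vegetation indices** (`rescale_reflectance()`,
   `compute_vi()`, `zonal_means()`): 4-band (B/G/R/NIR) scenes arrive
   as scaled integers (reflectance x 10,000) and are divided by 10,000
   before any index is computed. Sixteen indices are supported, eight
   visible-band ("RGB") and eight NIR-based; `vi_definitions()` lists
   the formulas. Subplot-level means are taken over the pixels whose
   centers fall inside each subplot (half-open rectangles), skipping
   undefined pixels (zero denominators become `NA`, never infinities,
   so downstream regressions stay finite).

2. **Yield-monitor cleaning** (`clean_yield()`): points outside the
   study area, with abnormal heading, grain moisture below 10% or above
   33%, or speed below 0.7 or above 8.2 mph are removed, as are points
   whose speed changed by more than 15% from the previous reading in
   the same pass. Remaining yields are standardized to 15% moisture
   (`wet * (1 - m/100) / 0.85`), and per-treatment outliers beyond 3
   standard deviations of the treatment mean (computed before removal,
   single pass) are dropped. Every removal carries a reason code and
   the audit report reconciles counts.

3. **VI-yield regression screening** (`run_regression_battery()`):
   one ordinary least-squares regression of subplot yield on subplot
   VI per (field, timing, VI) combination; fit quality is reported as
   `R^2 = 1 - RSS/TSS`, RMSE, and nRMSE (RMSE divided by the observed
   yield range, to compare across sites), with `p < 0.10` on the slope
   t-test as the significance rule. The battery always enumerates
   `fields x timings x VIs` rows; degenerate cells are flagged, not
   dropped.

4. **Plateau response curves and AONR** (`run_curve_battery()`): per
   transect, timing, and VI (vegetative timings only, by default 1-3),
   both a linear-plateau (`y = a + b min(x, x0)`) and a
   quadratic-plateau (`y = a + bx + cx^2` up to the smooth vertex
   `x0 = -b/(2c)`, constant beyond) curve are fitted to the five
   subplot observations. Screens run in order: convergence, `R^2 >
   0.50` (strict), and agronomic plausibility (positive slope for the
   linear family, concave-down curvature for the quadratic). Among
   passers the lower AIC wins; an exact tie goes to the quadratic
   plateau. The selected join point is the candidate AONR; if it
   exceeds the maximum tested rate the curve is discarded. The
   identical procedure applied to yield-versus-N gives AONRy.

5. **Agreement** (`aonr_pairs()`, `agreement_stats()`): every retained
   VI curve is paired with its transect's AONRy; accuracy is the
   signed percent difference `(AONRvi - AONRy)/AONRy * 100`, plus the
   squared Pearson correlation, RMSE, and MAE over pairs, grouped by
   field, timing, index, or spectral group.

`run_pipeline()` executes all stages from one seeded configuration and
`enumerate_design()` reports the design arithmetic (for the default
three-trial, seven-timing design: 336 regressions, of which 144
vegetative and 192 reproductive, and 1,152 VI-N curves -- 384 per field
and 72 per VI).

## The plateau fitter

Both families are fitted by profiling the join point: conditional on
`x0`, each model is exact OLS on a single constructed regressor
(`min(x, x0)` for the linear family; `x - x^2/(2 x0)` below the join
and `x0/2` above for the quadratic). The profile RSS is evaluated in
one vectorized pass over a dense grid of 2,001 candidates plus the
observed rates, and the winning bracket (and any bracket within a
relative `1e-6` of it) is polished with a bounded golden-section
optimizer. The grid must be dense: the profile is only piecewise smooth
-- it has kinks where `x0` crosses a data point -- and can carry several
near-tied local minima; a coarse grid with a single local refinement
demonstrably misses the global optimum on random 5-point data. The test
suite certifies the fitter against an exhaustive two-stage grid oracle
to within `1e-8` relative RSS on 200 random datasets.

Numerical choices worth knowing:

* **Centered OLS.** The vectorized sweep uses explicitly centered
  sums and explicit residuals. The textbook one-pass shortcut
  (`S_yy - S_zy^2/S_zz`) loses catastrophically when a candidate join
  makes the regressor nearly constant and can report spurious perfect
  fits.
* **Machine-zero ties.** An RSS at machine-precision level
  (`rss <= 1e-10 * tss`) is floored to zero in the AIC. With five
  observations and at most two rates on the rising limb, *both*
  families interpolate the data exactly; comparing their floating-point
  RSS residue would pick a family arbitrarily, whereas the tie rule
  (prefer the quadratic) was designed for exactly this situation.
* **Join-point ranges.** The linear-plateau join is constrained to the
  tested rate range (a strictly rising response pins it to the maximum
  rate, flagged `boundary`). The quadratic vertex may fall up to 1.5x
  the maximum rate: an optimum beyond the tested range is a legitimate
  fit outcome that the exceeds-maximum rule must be able to discard.
* **Convexity.** The smooth-join family cannot represent convex
  curvature (`c = -b/(2 x0)` has the sign of `-b`), so the fitter also
  solves the unconstrained parabola; when the data are convex and the
  parabola fits better, that solution (with `c >= 0` and no join) is
  reported so screening rejects it with `not_concave_down`.
* **AIC form.** `AIC = n ln(RSS/n) + 2(p + 1)` with `p = 3` for both
  families, counting the error variance as a parameter. Since both
  families have equal `p` and `n`, selection reduces to comparing RSS;
  the formula choice is therefore inert for this design, but it is
  stated so the reported AIC values are interpretable.
* **Identifiability.** A 5-rate transect identifies the join point only
  when at least two distinct rates lie strictly below it; with one, a
  one-parameter family of curves interpolates exactly and the reported
  join is arbitrary within an interval. Parameter-recovery tests
  condition on the identified regime; real analyses should treat
  near-boundary AONR estimates with the same caution.

## The synthetic field-trial generator

`sim_config()` describes a virtual study; the defaults emulate a
three-trial on-farm design: one strip-till trial with rates
44/89/155/222/289 kg/ha (20-130% of a 222 kg/ha farmer rate) and two
conventionally tilled trials (111/111/155/222/289 and 90/90/126/180/234
kg/ha; the duplicated 50% rate appears as two distinct subplots, so
every transect holds five subplots). Eight transects per trial, 55 m x
18.29 m subplots, 1.5 m buffers between adjacent subplots, 15 m between
consecutive ones, 3-m pixels, and seven timings (V7-V8 through R6;
timings 1-3 are the vegetative window).

Ground truth: each transect draws a true AONR from a normal
distribution (default mean 80% of the farmer rate, sd 20-25 kg/ha,
truncated to the positive range up to the maximum rate) and yield
parameters around 7.5 Mg/ha at zero N rising to a ~13 Mg/ha plateau,
following a configurable plateau family (quadratic by default).

Scenes are rendered by per-pixel linear spectral mixing:
`reflectance = f * canopy + (1 - f) * (r * residue + (1 - r) * soil)`,
where `r` is the trial's residue fraction (0.70/0.30/0.10 across the
three default trials, encoding the tillage contrast) and `f` is the
subplot's canopy fraction: logistic growth over the timing index
(`1/(1 + exp(-1.2 (t - 2.5)))`) scaled by N sufficiency
`min(1, N/AONR)^gamma` (default `gamma = 0.5`, diminishing returns).
The endmember spectra are synthetic but plausible values for green
canopy, bare soil, and dry residue; they ship as a config block, not
hard-coded truth. Output scenes follow the scaled-integer convention
(x 10,000, clipped to 0-10000, 16-bit), written as multiband TIFF with
a JSON sidecar carrying the affine transform and band order.

Yield-monitor streams run harvest passes the full length of each
treatment strip, so points naturally fall in the buffers between
subplots (and are then outside every zone). Clean points have slowly
varying speed (steps under 5%), headings within a few degrees of the
pass direction, and moisture well inside 10-33%. A configurable
fraction of in-subplot points receives injected artifacts --
out-of-range moisture or speed, a 25% speed jump, a heading spike, or a
gross yield outlier -- each tagged with a hidden truth label so filter
recall is measurable. Artifact injection uses a random stream separate
from field-truth generation, so changing the artifact rate never
perturbs the underlying field. One consequence of the speed-change rule
as stated (compare to the previous *recorded* reading) is that the
clean point following an out-of-range-speed artifact legitimately shows
a >15% change and is flagged; false-positive checks therefore use
streams without speed-class artifacts.

What the generator does *not* emulate: radiative transfer, atmospheric
or georeferencing error, spatial autocorrelation of soil within
transects, weather, pests, lodging, or economic considerations. Passing
tests on synthetic trials therefore certify the *pipeline machinery* --
formulas, screens, selection rules, bookkeeping -- not the field-scale
performance of satellite VIs, which depends on everything the generator
abstracts away.

## Decisions where the design was open

* **Unit of observation.** Each subplot is one observation (mean VI vs
  mean cleaned yield); duplicated 50%-rate subplots enter response
  curves as two observations at one rate rather than being averaged,
  matching the five-observations-per-transect structure.
* **Outlier grouping.** The 3-sd yield screen groups by treatment
  within field by default; `outlier_by = "treatment_within_transect"`
  switches it.
* **Abnormal heading** is undefined in the field vocabulary; it is
  implemented as a deviation of more than 30 degrees (configurable)
  from the pass's circular median heading.
* **Idempotent cleaning.** The speed-jump and heading references are
  computed once from the original sequence and carried as columns, so
  re-filtering an already-filtered table removes nothing further.
* **Buffer pixels** are excluded from subplot means by construction
  (zones contain only in-subplot pixels); the explicit pixel-level zone
  table makes the opposite choice reproducible if wanted.
* **Yield-curve screening** applies the same `R^2 > 0.50` and
  plausibility criteria as the VI curves; transects whose yield curve
  fails contribute no agreement pairs.
* **Agreement means** over pairs are unweighted; per-field summaries
  are emitted alongside so any reweighting remains possible.
* **Yield-point density** is a parameter
  (`yield_points_per_subplot`, default 30) rather than an assumption.

## Validation suite and problem sizes

The test suite ties every stage to an independent oracle: a per-pixel
scalar evaluator for all sixteen VI formulas (agreement to `1e-12`);
`lm()` for the regression statistics; the exhaustive grid oracle for
the plateau fitter (200 random datasets, `1e-8` relative); hand
arithmetic for the moisture, AIC, percent-difference, RMSE and MAE
examples; and hidden truth labels for cleaning recall (100% on
range-based rules). Distributional checks use 10,000 null regressions
for the `p < 0.10` type-I rate and 500 simulated transects for AONR
recovery (median error within 10% of the tested N range at 5%-of-range
noise; essentially exact at zero noise). These sizes keep the whole
suite around two minutes while leaving the Monte-Carlo margins far from
their thresholds.

The end-to-end check deserves a note. With reflectance noise, yield
noise, and artifacts all at zero, a run of the full pipeline should
return AONRvi = AONRy. This is exactly true only for band-linear
indices (EXG, the green-red difference, the green band): a linear
spectral mixture makes any *linear* band combination an affine function
of canopy fraction, hence of `min(N/AONR, 1)` when `gamma = 1`, so the
VI-N curve is in the same plateau family as the yield-N curve with the
same join point. Ratio indices (NDVI and friends) are Moebius functions
of the canopy fraction -- monotone but curved -- so their zero-noise
join points differ slightly from the truth by construction. The
acceptance test therefore runs the linear-plateau yield family with
`gamma = 1`, restricts pairs to EXG and the green-red difference, and
requires the optimum windows that keep three rates on the rising limb
(the identified regime). The residual disagreement it tolerates (mean
percent difference below 0.5%, squared correlation above 0.99) is the
footprint of the scaled-integer convention: rounding reflectance to 1
part in 10,000 perturbs early-season VI-N slopes enough to move join
points by a few kg/ha. That quantization is part of the data format,
not of the optimizer.

## Limitations

* The pipeline estimates agronomic, not economic, optima; price ratios
  are out of scope.
* No confidence intervals on AONR are provided (a bootstrap would be
  the natural extension).
* Red-edge and SWIR indices are not implemented; the index set is
  fixed to the sixteen 4-band formulas.
* Scene I/O targets the package's own TIFF + JSON-sidecar dialect and
  generic band matrices; full GeoTIFF tag handling and CRS workflows
  are out of scope.
* The multiple regressions are reported without multiplicity
  correction, mirroring the screening character of the analysis.
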