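# aonrvi

Estimating in-season agronomic optimum nitrogen rates for corn from
satellite vegetation indices.

## What this package does

Growers who sidedress nitrogen must decide on a rate during the
vegetative window, but the yield-based agronomic optimum N rate (AONR)
— the rate at which the yield–N response curve reaches its plateau — is
only known after harvest. On-farm calibration strips imaged by 3-m
multispectral satellites offer an in-season alternative: fit the same
plateau response to a vegetation index (VI) instead of yield and read
off a VI-based optimum, AONRvi.

`aonrvi` is a tidyverse-style R implementation of that analysis for
strip-trial designs (transects of adjacent subplots spanning 4–5 N
rates, multiple image timings, combine yield monitors). It provides:

* the sixteen standard 4-band (Blue/Green/Red/NIR) vegetation indices,
  computed from scaled-integer surface reflectance with per-subplot
  zonal means;
* yield-monitor cleaning with the standard range, speed-change,
  heading, and ±3 sd rules, moisture standardization to 15%, and a full
  audit trail;
* the VI–yield regression battery (one OLS fit per field × timing × VI,
  with R², nRMSE, and the p < 0.10 screen);
* linear-plateau and quadratic-plateau response fitting per transect,
  with the R² > 0.50 retention screen, agronomic-plausibility screens
  (positive slope / concave-down), AIC selection with the
  quadratic-preferred tie rule, and the discard rule for optima beyond
  the tested range:

  `y = a + b·min(N, x0)`  (linear plateau)
  `y = a + bN + cN²` for `N < x0 = −b/(2c)`, constant beyond  (quadratic plateau)

* AONRvi vs AONRy agreement: signed percent difference
  `(AONRvi − AONRy)/AONRy × 100`, Pearson r², RMSE, and MAE by field,
  timing, index, and spectral group;
* a synthetic field-trial generator (spectral-mixture scenes over
  canopy/soil/residue endmembers, plateau yield responses, realistic
  yield-monitor streams with labeled injected artifacts) so the whole
  pipeline is testable without field data.

See `vignettes/aonrvi-methods.Rmd` for the models, numerical choices,
and what the synthetic trials do and do not certify.

## Worked example

Fit both plateau families to one transect's yields and apply the
selection rules:

```r
library(aonrvi)

x <- c(44, 89, 155, 222, 289)        # N rates, kg/ha
y <- c(8.1, 10.4, 12.4, 12.9, 12.8)  # yields, Mg/ha

lp <- fit_linear_plateau(x, y)
qp <- fit_quadratic_plateau(x, y)
glance(qp)
#>   family             x0 plateau r_squared     rss   aic n_obs converged boundary
#> 1 quadratic_plat…  204.    12.8     1.000 0.00503 -26.5     5 TRUE      FALSE

screen_and_select(lp, qp, max_n_rate = 289)
#>   lp_verdict qp_verdict lp_r2 qp_r2 lp_aic qp_aic lp_x0 qp_x0 selected
#> 1 pass       pass       0.992 1.000  -9.88  -26.5  134.  204. quadratic_plateau
```

Both families pass the screens; the quadratic plateau wins on AIC, so
this transect's AONRy is its join point, 204 kg/ha. (The two families
genuinely disagree here — 134 vs 204 kg/ha — which is why the selection
rules matter.)

A full simulated study, end to end:

```r
run <- run_pipeline(sim_config(seed = 42))
run
#> <aonrvi_run>
#> <enumeration_report>
#>   regression models: 336 total (144 vegetative, 192 reproductive)
#>   VI-N curves: 1152 total, 384 per trial, 72 per VI (24 transects)
#>   curves retained: 880 / 1152 (76.4%)
#>   AONR agreement: n = 852 pairs, mean % diff = 26.3, R^2 = 0.20, RMSE = 53.7 kg/ha, MAE = 41.9 kg/ha

run$retention$by_field
#>   trial_id n_curves n_usable pct_usable
#> 1 ST-S          384      325       84.6
#> 2 CT-C          384      289       75.3
#> 3 CT-S          384      266       69.3
```

The enumeration block is the design arithmetic (3 fields × 7 timings ×
16 VIs regressions; 24 transects × 3 vegetative timings × 16 VIs
response curves). Retention is the share of VI–N curves that survived
the R², plausibility, and exceeds-maximum screens; the agreement line
summarizes how far the surviving VI-based optima sit from the
yield-based ones (synthetic trials are far cleaner than real fields, so
retention is high here). `plot_r2_heatmap()`, `plot_retention()`, and
`plot_aonr_agreement()` draw the corresponding figures, and
`run_pipeline(..., out_dir = "run1")` writes every stage table as CSV
plus a JSON report.

Real data enter through the same surfaces: `read_scene()` /
`spectral_scene()` for imagery, a pixel→subplot zone table for
`zonal_vi_table()`, and a points CSV for `clean_yield()`.

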