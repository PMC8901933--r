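# cgrvar

Analysis of long-term variability in the atmospheric CO2 growth rate
(CGR) and its link to tropical extreme droughts — for carbon-cycle and
climate scientists who want the full chain as tested, reusable R
functions rather than one-off scripts.

The package implements:

* **Moving-window climate sensitivities.** Nine competing linear models
  (M1-M9) of detrended CGR anomalies on tropical climate anomalies
  (temperature MAT, precipitation MAP, radiation RAD, water storage TWS,
  lagged precipitation), fitted on 20-year moving windows:
  `dCGR = gamma_T dMAT + gamma_W dMAP + gamma_R dRAD (+ interaction) + e`,
  with adjusted R2, AIC (`n log(RSS/n) + 2k`), variance inflation factors,
  and bootstrap coefficient uncertainty from the 0.2 PgC yr-1 CGR
  observational error (100 replicates).
* **Percentile drought mapping.** Each pixel's monthly precipitation is
  ranked against its own record; severity bands at the 1/10/25/50th local
  percentiles (very extreme / extreme / mild / natural deficit). The
  drought-affected area of a window is the frequency-weighted,
  cos-latitude-area-weighted fraction of tropical vegetated land in a
  band, plus hotspot masks (pixels in-band >10% of the time) and
  continent/biome breakdowns.
* **Autocorrelation control.** Durbin-Watson statistic
  `DW = sum(diff(e)^2)/sum(e^2)`, lag-1 rho estimation, single-pass
  Cochrane-Orcutt quasi-differencing `y_i - rho y_{i-1}`, an adjusted
  bivariate regression, and the independent 5-year-segment analysis.
* **Attribution and partition.** Windowed STD of CGR, the regression of
  STD on extreme-drought area (slope in PgC yr-1 per % area, with and
  without intercept), and a time-for-space partition of the predicted STD
  into regional contributions using an NEE-magnitude spatial weight —
  conserving the pantropic total exactly.
* **A seeded synthetic-data generator** for the annual tropical climate
  system (with the empirical cross-correlations, e.g. MAP-water 0.68),
  a CGR series with known generating coefficients (default
  `gamma_T = 5.49` PgC yr-1 K-1), gridded gamma-distributed monthly
  precipitation with controllable drought epochs, and region masks — so
  the whole pipeline is testable offline with known ground truth.

See the methods vignette (`vignettes/cgr-variability-methods.Rmd`) for
models, parameter choices and limitations.

## Worked example

Moving-window temperature sensitivity on a synthetic 1959-2016 system
(generating `gamma_T = 5.49`, CGR noise 0.2 PgC yr-1, Pinatubo years
1991-1993 excluded):

```r
library(cgrvar)
climate <- gen_climate_series(climate_system_spec(seed = 1))
cgr     <- gen_cgr(climate, cgr_generator_spec(seed = 2))
windows <- enumerate_windows(1959, 2016, 20, excluded_years = 1991:1993)
scan    <- moving_sensitivity("M1", cgr, climate, windows)
head(scan[, c("start_year", "end_year", "gamma_T", "gamma_T_se",
              "significant_05")], 3)
#>   start_year end_year  gamma_T gamma_T_se significant_05
#> 1       1959     1978 6.058943  0.3107769           TRUE
#> 2       1960     1979 6.064806  0.3438510           TRUE
#> 3       1961     1980 6.132361  0.3872206           TRUE

bootstrap_sensitivity("M1", cgr, climate, window = windows[22, ],
                      reps = 100, noise_sd = 0.2, seed = 3)
#>          term      estimate      boot_se         lower        upper
#> 2         MAT  5.427976e+00 3.041632e-01  4.928444e+00 6.070708e+00
#> 3         MAP -2.141888e-03 1.506520e-03 -4.771879e-03 7.477864e-04
#> 4         RAD  6.018485e-02 2.961637e-02  1.490297e-02 1.207674e-01
```

Each window's `gamma_T` estimate (PgC yr-1 K-1) stays within its
bootstrap interval of the generating 5.49, and is significant at
p < 0.05 throughout — the windowed estimates wobble around the constant
truth because each window sees 20 noisy years.

Drought mapping and STD attribution, with CGR variability tied to the
drought-affected area at a known slope of 0.14 PgC yr-1 per % area:

```r
n_years <- 200L; n_months <- n_years * 12L; third <- n_months %/% 3L
grid <- gen_precip_grid(precip_grid_spec(
  n_lat = 10, n_lon = 20, n_months = n_months, start_year = 2000,
  epochs = list(list(from = third + 1L, to = 2L*third, multiplier = 0.75),
                list(from = 2L*third + 1L, to = n_months, multiplier = 0.55)),
  seed = 6))
mask <- gen_masks_and_weights(n_lat = 10, n_lon = 20, seed = 7)
cats <- classify_drought(pixel_percentiles(grid))
wins <- enumerate_windows(2000, 2199, 20, step = 20)
area <- windowed_drought_area(cats, mask, wins)   # % of vegetated area
set.seed(8)
cgr2 <- annual_series(2000:2199, unlist(lapply(seq_len(nrow(wins)),
  function(i) rnorm(20, 0, 0.14 * area$fraction[i]))), units = "PgC yr-1")
std <- std_windows(cgr2, wins, detrend_within = FALSE)
regress_std_on_area(std, area)
#> <attribution_fit> STD ~ area[very_extreme+extreme], n = 10 windows
#>   with intercept:    slope = 0.1363 PgC yr-1 %-1 (se 0.0211), r2 = 0.839, p = 0.000195
#>   without intercept: slope = 0.1481 PgC yr-1 %-1 (se 0.0073)
```

The epochs drive the extreme + very extreme area from ~5.6% up to ~15%
of vegetated land, and the regression recovers the generating slope
within two standard errors. `partition_regions()` then splits each
period's predicted STD across continents with NEE weights, conserving
the total.

A full staged run (simulate → preprocess → sensitivity → drought →
attribute → report) is available as `run_pipeline(pipeline_config())`,
or from the shell via `inst/scripts/cgr_pipeline.R`; every stage writes
CSV/JSON artifacts plus a log of the seed and configuration hash.

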