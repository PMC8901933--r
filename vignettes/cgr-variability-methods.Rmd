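---
title: "Methods: CGR variability, climate sensitivities and tropical extreme droughts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGR variability, climate sensitivities and tropical extreme droughts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrvar)
```

## The scientific problem

The atmospheric CO2 growth rate (CGR, PgC yr-1) varies strongly from year
to year, mostly because the tropical land carbon sink responds to climate.
Two standard summaries of that behaviour are

* the *apparent climate sensitivities* of CGR — regression coefficients of
  detrended CGR anomalies on tropical climate anomalies (temperature
  `gamma_T`, water `gamma_W`, radiation `gamma_R`) estimated in moving
  multi-year windows; and
* the *variability magnitude* STD_CGR — one sample standard deviation of
  CGR within each moving window.

Both quantities drift over decades. The hypothesis this package
operationalises is that the drift in STD_CGR (and through it the apparent
drift in `gamma_T`) tracks the fraction of tropical vegetated area under
*extreme meteorological drought*, defined from local monthly precipitation
percentiles. The package provides every stage as a tested, reusable
function: synthetic data generation, preprocessing, the nine competing
sensitivity regressions, percentile drought mapping, autocorrelation
corrections, STD attribution and the regional partition.

## Models and procedures

### Sensitivity models M1-M9

Nine linear structures relate CGR anomalies to climate anomalies
(see `model_terms()`): multivariate models combining tropical mean annual
temperature (MAT), precipitation (MAP), shortwave radiation (RAD),
terrestrial water storage (TWS) and 4-month-lagged precipitation (MAPlag),
with optional temperature-water interaction terms, plus three univariate
models. Anomalies are departures from an ordinary least-squares linear
trend against calendar year. Within each moving window (default 20 years,
step 1) the response and predictors are detrended over exactly the years
entering the fit, so every window's predictors are mean-zero; globally
excluded years (default 1991-1993, the volcanically perturbed CGR years)
are dropped from fits while windows keep their nominal span. Interaction
terms are products of anomalies z-scored within the window — the
normalisation makes interaction coefficients comparable across windows.

All models carry an intercept (per-window exclusions break exact zero
means). Diagnostics per fit: adjusted R2; AIC in the Gaussian-likelihood
form `n*log(RSS/n) + 2k` with `k` counting slopes, intercept and the
residual variance (the additive constant is conventional, so only AIC
*ranks* are meaningful and only ranks are asserted in tests); and variance
inflation factors `VIF_j = 1/(1 - R2_j)` from auxiliary regressions of
each predictor on the others (undefined for univariate models). Large VIF
flags the collinearity that destabilises windowed coefficients; the
comparison table marks the lowest-collinearity multivariate structures.

Coefficient uncertainty from CGR observational error is bootstrapped: each
replicate (default 100) perturbs the raw CGR series with i.i.d.
`N(0, 0.2^2)` PgC yr-1 noise, re-detrends and refits; the bootstrap SE is
the across-replicate standard deviation, with percentile intervals. The
default perturbs-then-detrends; detrending first is available by passing
anomalies with `detrend = FALSE`.

### Drought mapping

Each pixel's monthly precipitation is converted to its empirical
percentile among that pixel's reference months, pooling all calendar
months (a month-of-year-specific option is deliberately not provided here;
pooled percentiles are the operative definition, and seasonality in the
synthetic generator is absent so the distinction does not arise). The
percentile of a month with average rank `r` among `n` reference months is
`100*(r - 0.5)/n`, so band occupation over the reference period matches
nominal widths up to the discreteness of `n`. Severity bands are half-open
percentile intervals: very extreme [0,1), extreme [1,10), mild [10,25),
natural water deficit [25,50), none [50,100].

Ties: percentiles use average ranks, and a pixel where more than 30% of
reference months share a single value (long strings of zeros on desert
margins) is flagged *degenerate* — its percentiles are undefined and it is
excluded from both numerator and denominator of area accounting, since
"drought" has no meaning where most months are identically dry.

Drought-affected area per window is frequency-weighted and area-weighted:
each vegetated, non-degenerate pixel contributes its cos-latitude area
times the fraction of the window's months in the band, and the regional
fraction is expressed as a percent of the total tropical vegetated area
(so continent fractions add up to the pantropic fraction; region-relative
denominators are available via `denominator = "region"`). Hotspots are
pixels in-band for strictly more than 10% of a window's months.

### Autocorrelation handling

Because moving windows overlap, windowed series (STD_CGR, 20-year climate
means) are serially correlated. The package implements the Durbin-Watson
statistic `DW = sum(diff(e)^2)/sum(e^2)` on trend residuals, lag-1 rho
estimation as the no-intercept OLS slope of `e_i` on `e_{i-1}` (matching
the residual model `e_i = rho*e_{i-1} + r_i`), and a single-pass
Cochrane-Orcutt quasi-difference `y_i - rho*y_{i-1}`. In
`adjusted_regression()` each variable is adjusted with its *own* rho
estimated from its own trend residuals (a shared-rho variant is a flag);
one pass only, since iterating to convergence is a different estimator
than the stated procedure. The independent-segment analysis
(`segment_analysis()`) offers the complementary route: 5-year
non-overlapping segments (a 58-year record yields twelve, the last
overlapping its predecessor by two years to fit the span). Per-segment
sensitivities use univariate fits — a 5-point segment cannot support a
4-parameter multivariate model under the minimum-observations rule
(n at least parameters + 2).

### Attribution and regional partition

`std_windows()` computes the windowed STD, by default of within-window
detrended values (the raw variant is retained because both conventions
are defensible; both can be reported). `regress_std_on_area()` fits
STD on the extreme + very extreme area fraction with and without an
intercept; the *without-intercept* slope (PgC yr-1 per % area) is used for
partitioning, encoding that zero drought area predicts zero
drought-driven variability.

The partition is a time-for-space substitution: for each period, the
pantropic predicted STD is `slope x mean pantropic area fraction`, split
across regions in proportion to `w_r * A_r`, where `A_r` is the region's
mean drought-area fraction and `w_r` the mean |NEE| weight over the
region's vegetated pixels (the magnitude of net ecosystem exchange; the
signed mean is a flag since NEE sign conventions differ across products).
The shares sum to one window by window, so regional contributions conserve
the pantropic prediction exactly; the quoted uncertainty is the standard
deviation of the per-window contributions inside the period, i.e.
propagated from within-period drought-area variability. The normalisation
of the spatial weight is an explicit design decision of this package —
conservation fixes it only up to the choice of `w_r`.

## The synthetic-data generator

The generator defines the study conditions for all tests; it is
first-class, seeded, and a pure function of its spec.

* **Climate system** (`gen_climate_series()`): 58 years of annual MAT,
  MAP, RAD, TWS as correlated Gaussians. Target cross-correlations use the
  empirical tropical values (MAT-MAP -0.15, MAT-water -0.23, MAP-water
  0.68); the radiation column (+0.30 with MAT, -0.35 with MAP, -0.25 with
  TWS) is not reported anywhere we could anchor it, so it encodes the
  usual tropical cloud coupling — sunnier is warmer and drier — at modest
  strength, chosen once. Interannual spreads (0.22 K, 45 mm yr-1,
  1.8 W m-2, 2.4 cm) and means are plausible tropical-land values.
* **CGR** (`gen_cgr()`): `trend*t + 5.49*dMAT - 0.003*dMAP + 0.05*dRAD +
  gamma_i*z(dMAT*dMAP) + N(0, 0.2^2)`, with anomalies defined by the same
  full-range detrending the estimators use, so generating and estimating
  conventions match. The default `gamma_T = 5.49` PgC yr-1 K-1 is the
  1980-1999 apparent sensitivity; the water and radiation defaults are
  small, consistent with water sensitivity being statistically weak in
  multivariate fits; noise 0.2 PgC yr-1 is the conventional CGR
  uncertainty.
* **Precipitation grid** (`gen_precip_grid()`): 20 x 40 pixels over
  23S-23N, 696 months, i.i.d. gamma marginals per pixel (shape 2, scale
  60 mm — positive, right-skewed, tie-free, so empirical percentiles are
  unambiguous). Nonstationary drought epochs multiply the gamma scale over
  disjoint month ranges; a multiplier below one is the single lever that
  pushes an epoch toward low local percentiles.
* **Masks and weights** (`gen_masks_and_weights()`): continents by
  longitude thirds, seeded random biomes (40% forest / 35% semi-arid /
  25% other), 90% vegetated, gamma-distributed nonnegative NEE weights.

What the generator does **not** emulate: ENSO or any spatially correlated
precipitation process, seasonality, vegetation dynamics, and the real
nonstationarities of observed records. Passing tests therefore demonstrate
that the estimators recover known structure under the stated stochastic
model — not that observational conclusions are correct.

## Numerical choices and degenerate inputs

* OLS uses a Cholesky solve of the normal equations (designs here have at
  most five columns); exactly collinear designs raise an error naming the
  predictors. Fits require at least `parameters + 2` observations.
* Detrending uses closed-form OLS and is idempotent to machine precision;
  missing values propagate as NA and are never silently dropped.
* Percentile band membership is half-open `[lo, hi)`; the top band closes
  at 100. Average ranks resolve ties; the >30% mode-share degeneracy rule
  removes pixels where percentiles are meaningless.
* All-zero residual vectors make DW undefined (error); `|rho| >= 1` is
  rejected for quasi-differencing; STD normalisation errors when the first
  window has zero STD (e.g. an exactly linear series under within-window
  detrending).
* Windows are labelled by start/end year; tables use the centre year.

## Problem sizes in the test suite

The checks run at desk scale by design: the drought calibration uses the
default 20 x 40 x 696 grid; bootstrap coverage uses 200 independent
20-year windows with 100 replicates each; the spurious-regression control
uses 500 AR(1) pairs of length 58 (rho 0.9); the AIC model-comparison
simulation averages over ten independent 50-year windows per seed, because
the mean-AIC separation of nested models relies on averaging over
*independent* fits; the end-to-end attribution run uses non-overlapping
20-year windows over multi-century synthetic records so that the
regression standard error used in the 2-SE recovery check is valid —
overlapping step-1 windows give serially correlated STD errors and an
anticonservative SE.

## Known limitations

* The pooled (all-calendar-month) percentile definition concentrates
  drought flags in dry seasons on real seasonal data; the synthetic
  generator has no seasonality, so tests cannot detect this. Real-data use
  should consider the consequences.
* Sensitivities from linear models are *apparent* sensitivities;
  collinearity and omitted nonlinearity move them, which is exactly why
  the model set spans nine structures and reports VIF.
* The regional partition depends on the chosen spatial-weight
  normalisation; alternative weights (e.g. biomass) would change regional
  shares while conserving the pantropic total.
* Gridded I/O uses a plain-text long-format CSV interchange
  (`lat,lon,year,month,value`); it is lossless and portable but verbose
  for large grids.
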