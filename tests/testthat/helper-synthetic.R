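# Shared fixture builders: everything is generated in code, seeded.

# A small trend-free climate system whose anomalies carry the target
# cross-correlations directly.
flat_climate_spec <- function(n_years = 58L, seed = 1L, ...) {
  climate_system_spec(n_years = n_years, seed = seed,
                      trend = c(MAT = 0, MAP = 0, RAD = 0, TWS = 0), ...)
}

# Climate + noiseless CGR with known coefficients, for exact-recovery tests.
noiseless_system <- function(n_years = 58L, seed = 1L,
                             gamma_T = 2, gamma_W = 0.01, gamma_R = 0.05) {
  climate <- gen_climate_series(flat_climate_spec(n_years, seed))
  cgr <- gen_cgr(climate, cgr_generator_spec(
    gamma_T = gamma_T, gamma_W = gamma_W, gamma_R = gamma_R,
    gamma_i = 0, noise_sd = 0, seed = seed))
  list(climate = climate, cgr = cgr,
       truth = c(MAT = gamma_T, MAP = gamma_W, RAD = gamma_R))
}

# Tiny stationary precipitation grid + aligned all-vegetated mask.
small_drought_world <- function(n_lat = 6L, n_lon = 9L, n_years = 30L,
                                seed = 1L, epochs = list()) {
  spec <- precip_grid_spec(n_lat = n_lat, n_lon = n_lon,
                           n_months = n_years * 12L, start_year = 2000L,
                           epochs = epochs, seed = seed)
  grid <- gen_precip_grid(spec)
  mask <- gen_masks_and_weights(n_lat = n_lat, n_lon = n_lon,
                                seed = seed + 1L, p_vegetated = 1)
  list(grid = grid, mask = mask, spec = spec)
}

# Seeded AR(1) series.
gen_ar1 <- function(n, rho, seed, sd = 1) {
  set.seed(seed)
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd / sqrt(1 - rho^2))
  for (i in 2:n) e[i] <- rho * e[i - 1] + rnorm(1, 0, sd)
  e
}
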