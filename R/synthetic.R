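#' Default cross-correlation of the tropical annual climate system
#'
#' Target interannual correlations among MAT, MAP, RAD and TWS. The
#' MAT-MAP (-0.15), MAT-TWS (-0.23, using soil-water as the storage analogue)
#' and MAP-TWS (0.68) entries are the empirical tropical values the generator
#' is built to emulate; the radiation column reflects the usual tropical
#' cloud coupling (sunnier years are warmer and drier) at modest strength.
#'
#' @return A 4x4 symmetric positive-definite correlation matrix with
#'   dimnames `MAT`, `MAP`, `RAD`, `TWS`.
#' @export
default_climate_correlation <- function() {
  vars <- c("MAT", "MAP", "RAD", "TWS")
  C <- diag(4)
  dimnames(C) <- list(vars, vars)
  C["MAT", "MAP"] <- C["MAP", "MAT"] <- -0.15
  C["MAT", "TWS"] <- C["TWS", "MAT"] <- -0.23
  C["MAP", "TWS"] <- C["TWS", "MAP"] <- 0.68
  C["MAT", "RAD"] <- C["RAD", "MAT"] <- 0.30
  C["MAP", "RAD"] <- C["RAD", "MAP"] <- -0.35
  C["TWS", "RAD"] <- C["RAD", "TWS"] <- -0.25
  C
}

#' Specification of the synthetic tropical climate system
#'
#' Defines an annual multivariate Gaussian climate system (MAT, MAP, RAD,
#' TWS) with prescribed climatological means, interannual standard
#' deviations, linear trends and cross-correlations. Defaults emulate the
#' 1959-2016 tropical (23S-23N) vegetated-land means: MAT ~25 degC with
#' ~0.2 K interannual spread and a warming trend, MAP ~1480 mm yr-1, RAD
#' ~205 W m-2, TWS anomalies in cm around zero.
#'
#' @param n_years Number of years.
#' @param start_year First calendar year.
#' @param means,interannual_sd,trend Named numeric vectors over
#'   `MAT, MAP, RAD, TWS` (units degC, mm yr-1, W m-2, cm; trends per year).
#' @param cross_correlation Symmetric positive-semi-definite correlation
#'   matrix with unit diagonal over the same variables.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return A list of class `climate_system_spec`.
#' @export
climate_system_spec <- function(
    n_years = 58L, start_year = 1959L,
    means = c(MAT = 25.2, MAP = 1480, RAD = 205, TWS = 0),
    interannual_sd = c(MAT = 0.22, MAP = 45, RAD = 1.8, TWS = 2.4),
    trend = c(MAT = 0.018, MAP = 0, RAD = 0, TWS = 0),
    cross_correlation = default_climate_correlation(),
    seed = 1L) {
  vars <- c("MAT", "MAP", "RAD", "TWS")
  stopifnot(n_years >= 2, all(vars %in% names(means)),
            all(vars %in% names(interannual_sd)),
            all(vars %in% names(trend)))
  if (any(interannual_sd < 0)) {
    stop("interannual_sd must be nonnegative", call. = FALSE)
  }
  C <- cross_correlation[vars, vars]
  if (max(abs(C - t(C))) > 1e-12 || max(abs(diag(C) - 1)) > 1e-12) {
    stop("cross_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("cross_correlation is not positive semi-definite", call. = FALSE)
  }
  structure(
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         means = means[vars], interannual_sd = interannual_sd[vars],
         trend = trend[vars], cross_correlation = C, seed = as.integer(seed)),
    class = "climate_system_spec"
  )
}

#' Generate the annual tropical climate series
#'
#' Draws `n_years` of correlated Gaussian anomalies via the Cholesky factor
#' of the target correlation matrix, scales by the interannual standard
#' deviations and adds means and linear trends.
#'
#' @param spec A [climate_system_spec()].
#' @return Named list of [annual_series()]: `MAT`, `MAP`, `RAD`, `TWS`.
#' @export
gen_climate_series <- function(spec) {
  stopifnot(inherits(spec, "climate_system_spec"))
  vars <- names(spec$means)
  # eigendecomposition handles the PSD-but-singular case chol() rejects
  eg <- eigen(spec$cross_correlation, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), length(vars))
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_years * length(vars)), spec$n_years)
  x <- z %*% t(L)
  t0 <- seq_len(spec$n_years) - 1L
  years <- spec$start_year + t0
  units <- c(MAT = "degC", MAP = "mm yr-1", RAD = "W m-2", TWS = "cm")
  out <- lapply(seq_along(vars), function(j) {
    v <- vars[j]
    annual_series(
      years,
      spec$means[[v]] + spec$trend[[v]] * t0 + spec$interannual_sd[[v]] * x[, j],
      units = units[[v]], label = v
    )
  })
  names(out) <- vars
  out
}

#' Specification of the synthetic CGR generator
#'
#' The CGR series is generated from the climate anomalies with a known
#' linear structure, so downstream sensitivity fits have a ground truth:
#' `CGR_t = trend*t + gamma_T*dMAT + gamma_W*dMAP + gamma_R*dRAD +
#' gamma_i*z(dMAT*dMAP) + eps`, `eps ~ N(0, noise_sd^2)`, where the `d`
#' anomalies are the inputs with their linear trends removed (the same
#' anomaly convention the estimators use) and `z()` is a z-score. Defaults:
#' `gamma_T = 5.49` PgC yr-1 K-1 (the 1980-1999 apparent temperature
#' sensitivity), a small negative water coefficient, and observation-level
#' noise of 0.2 PgC yr-1, the conventional CGR uncertainty.
#'
#' @param gamma_T,gamma_W,gamma_R,gamma_i Generating coefficients
#'   (PgC yr-1 per K, per mm yr-1, per W m-2, per interaction z-unit).
#' @param noise_sd Residual standard deviation, PgC yr-1.
#' @param trend Linear trend in CGR, PgC yr-2.
#' @param seed RNG seed for the noise.
#' @return A list of class `cgr_generator_spec`.
#' @export
cgr_generator_spec <- function(gamma_T = 5.49, gamma_W = -0.003,
                               gamma_R = 0.05, gamma_i = 0,
                               noise_sd = 0.2, trend = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(
    list(gamma_T = gamma_T, gamma_W = gamma_W, gamma_R = gamma_R,
         gamma_i = gamma_i, noise_sd = noise_sd, trend = trend,
         seed = as.integer(seed)),
    class = "cgr_generator_spec"
  )
}

#' Generate a synthetic CGR series from climate series
#'
#' @param climate Named list of [annual_series()] with at least `MAT`,
#'   `MAP`, `RAD`, sharing one year axis.
#' @param spec A [cgr_generator_spec()].
#' @return An [annual_series()] in PgC yr-1 labelled `CGR`.
#' @export
gen_cgr <- function(climate, spec) {
  stopifnot(inherits(spec, "cgr_generator_spec"))
  years <- climate[[1]]$year
  for (s in climate) {
    if (!identical(s$year, years)) {
      stop("climate series must share the same year axis", call. = FALSE)
    }
  }
  an <- lapply(climate, function(s) detrend_vector(s$year, s$value))
  t0 <- years - years[1]
  inter <- an$MAT * an$MAP
  inter_z <- if (spec$gamma_i != 0) {
    (inter - mean(inter)) / stats::sd(inter)
  } else 0
  set.seed(spec$seed)
  eps <- if (spec$noise_sd > 0) stats::rnorm(length(years), 0, spec$noise_sd)
         else 0
  cgr <- spec$trend * t0 + spec$gamma_T * an$MAT + spec$gamma_W * an$MAP +
    spec$gamma_R * an$RAD + spec$gamma_i * inter_z + eps
  annual_series(years, cgr, units = "PgC yr-1", label = "CGR")
}

#' Specification of the synthetic monthly precipitation grid
#'
#' Each pixel draws independent gamma-distributed monthly precipitation
#' (positive, right-skewed, almost surely tie-free, so empirical percentiles
#' are unambiguous). Nonstationary drought epochs are imposed by multiplying
#' the gamma scale (hence the mean) over a range of months; multipliers
#' below one push that epoch's months toward low local percentiles. The
#' default grid is 20 x 40 pixels over 23S-23N and 58 years (696 months).
#'
#' @param n_lat,n_lon Grid shape.
#' @param lat_range Latitude extent (degrees), pixel centres inside it.
#' @param n_months Number of months; must be a multiple of 12.
#' @param start_year First calendar year.
#' @param shape,scale Gamma marginal parameters (monthly totals, mm).
#' @param epochs List of `list(from, to, multiplier)` month ranges (1-based,
#'   inclusive) with positive mean multipliers; ranges must be disjoint.
#' @param seed RNG seed.
#' @return A list of class `precip_grid_spec`.
#' @export
precip_grid_spec <- function(n_lat = 20L, n_lon = 40L,
                             lat_range = c(-23, 23),
                             n_months = 696L, start_year = 1959L,
                             shape = 2, scale = 60,
                             epochs = list(), seed = 1L) {
  if (n_months %% 12L != 0L) {
    stop("n_months must be a multiple of 12", call. = FALSE)
  }
  if (length(epochs)) {
    covered <- integer(0)
    for (e in epochs) {
      stopifnot(all(c("from", "to", "multiplier") %in% names(e)))
      if (e$multiplier <= 0) {
        stop("epoch multipliers must be positive", call. = FALSE)
      }
      if (e$from < 1 || e$to > n_months || e$from > e$to) {
        stop("epoch month range outside 1..n_months", call. = FALSE)
      }
      rng <- seq(e$from, e$to)
      if (length(intersect(covered, rng))) {
        stop("epochs must cover disjoint month ranges", call. = FALSE)
      }
      covered <- c(covered, rng)
    }
  }
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         lat_range = as.numeric(lat_range), n_months = as.integer(n_months),
         start_year = as.integer(start_year), shape = shape, scale = scale,
         epochs = epochs, seed = as.integer(seed)),
    class = "precip_grid_spec"
  )
}

#' Generate a synthetic monthly precipitation grid
#'
#' @param spec A [precip_grid_spec()].
#' @return A [monthly_grid()] of monthly precipitation (mm).
#' @export
gen_precip_grid <- function(spec) {
  stopifnot(inherits(spec, "precip_grid_spec"))
  half <- diff(spec$lat_range) / spec$n_lat / 2
  lat <- seq(spec$lat_range[1] + half, spec$lat_range[2] - half,
             length.out = spec$n_lat)
  lon <- seq(-180 + 360 / spec$n_lon / 2, 180 - 360 / spec$n_lon / 2,
             length.out = spec$n_lon)
  scale_m <- rep(spec$scale, spec$n_months)
  for (e in spec$epochs) {
    scale_m[seq(e$from, e$to)] <- spec$scale * e$multiplier
  }
  set.seed(spec$seed)
  n_pix <- spec$n_lat * spec$n_lon
  # month-major fill so each month's scale multiplies a full pixel slab
  vals <- stats::rgamma(n_pix * spec$n_months, shape = spec$shape,
                        scale = rep(scale_m, each = n_pix))
  monthly_grid(lat, lon,
               array(vals, dim = c(spec$n_lat, spec$n_lon, spec$n_months)),
               start_year = spec$start_year, units = "mm")
}

#' Generate a synthetic region mask and NEE weight map
#'
#' Assigns each pixel a continent by longitude thirds (tropical America,
#' Africa, Asia), a seeded random biome (forest / semi-arid / other), a
#' vegetated flag, and a nonnegative NEE-magnitude weight drawn from a gamma
#' distribution. Labels partition the vegetated area.
#'
#' @param n_lat,n_lon Grid shape.
#' @param lat_range Latitude extent (degrees).
#' @param seed RNG seed.
#' @param p_vegetated Probability a pixel is vegetated.
#' @param biome_probs Probabilities for `forest`, `semi_arid`, `other`.
#' @return A [region_mask()] with `nee_weight` filled in.
#' @export
gen_masks_and_weights <- function(n_lat = 20L, n_lon = 40L,
                                  lat_range = c(-23, 23), seed = 1L,
                                  p_vegetated = 0.9,
                                  biome_probs = c(forest = 0.40,
                                                  semi_arid = 0.35,
                                                  other = 0.25)) {
  half <- diff(lat_range) / n_lat / 2
  lat <- seq(lat_range[1] + half, lat_range[2] - half, length.out = n_lat)
  lon <- seq(-180 + 360 / n_lon / 2, 180 - 360 / n_lon / 2,
             length.out = n_lon)
  set.seed(seed)
  n_pix <- n_lat * n_lon
  cont_of_lon <- cut(seq_len(n_lon), breaks = 3,
                     labels = c("T.America", "T.Africa", "T.Asia"))
  continent <- matrix(rep(as.character(cont_of_lon), each = n_lat),
                      n_lat, n_lon)
  biome <- matrix(sample(names(biome_probs), n_pix, replace = TRUE,
                         prob = biome_probs), n_lat, n_lon)
  vegetated <- matrix(stats::runif(n_pix) < p_vegetated, n_lat, n_lon)
  nee <- matrix(stats::rgamma(n_pix, shape = 2, scale = 0.5), n_lat, n_lon)
  continent[!vegetated] <- NA
  biome[!vegetated] <- NA
  region_mask(lat, lon, continent, biome, vegetated, nee)
}
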