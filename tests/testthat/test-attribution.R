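test_that("windowed STD handles constants, trends and white noise correctly", {
  w <- enumerate_windows(2000, 2039, 20)
  set.seed(4)
  near_lin <- annual_series(2000:2039, 3 + 0.5 * (0:39) + rnorm(40, 0, 1e-6))
  # within-window detrending strips the ramp almost entirely
  expect_true(all(std_windows(near_lin, w)$std < 1e-5))
  # an exact ramp detrends to all-zero STDs, where normalisation is undefined
  lin <- annual_series(2000:2039, 3 + 0.5 * (0:39))
  expect_error(std_windows(lin, w), "first-window STD is zero")
  expect_error(std_windows(annual_series(2000:2039, rep(2, 40)), w),
               "first-window STD is zero")
  # raw (undetrended) STD of a pure ramp is the known closed form
  raw <- std_windows(lin, w, detrend_within = FALSE)
  expect_equal(raw$std, rep(0.5 * sd(1:20), nrow(w)), ignore_attr = TRUE)

  # seeded white noise sd 1: windowed STDs average to 1
  set.seed(9)
  wn <- annual_series(1800:2039, rnorm(240))
  wins <- enumerate_windows(1800, 2039, 20)
  s <- std_windows(wn, wins, detrend_within = FALSE)
  expect_equal(mean(s$std), 1, tolerance = 0.05)

  # normalized series times the first STD reproduces the raw series
  expect_equal(s$normalized * s$std[1], s$std, tolerance = 1e-12)
  expect_equal(s$normalized[1], 1)
})

test_that("STD excludes flagged years from its windows", {
  set.seed(10)
  v <- rnorm(40)
  ser <- annual_series(2000:2039, v)
  w_excl <- enumerate_windows(2000, 2039, 20, excluded_years = 2010)
  s <- std_windows(ser, w_excl, detrend_within = FALSE)
  manual <- sd(v[setdiff(1:20, 11)])
  expect_equal(s$std[1], manual)
})

test_that("STD-on-area regression recovers a constructed 0.14 slope", {
  set.seed(71)
  n <- 39
  area <- runif(n, 5, 10) # percent of vegetated area
  std_vals <- 0.14 * area + rnorm(n, 0, 0.02)
  wdf <- enumerate_windows(1959, 1959 + 19 + n - 1, 20)
  std <- structure(
    data.frame(start_year = wdf$start_year, end_year = wdf$end_year,
               center_year = wdf$center_year, std = std_vals,
               n = 20, normalized = std_vals / std_vals[1]),
    class = c("std_series", "data.frame"))
  areas <- data.frame(start_year = wdf$start_year, end_year = wdf$end_year,
                      region = "pantropic", band = "very_extreme+extreme",
                      fraction = area)
  fit <- regress_std_on_area(std, areas)
  expect_equal(fit$slope_no_intercept, 0.14, tolerance = 0.02 / 0.14)
  expect_equal(fit$slope, 0.14, tolerance = 0.05)
  # zero-intercept truth: with/without intercept slopes agree within 1 SE
  expect_lt(abs(fit$slope - fit$slope_no_intercept), fit$se)
  expect_gt(fit$r2, 0.9)

  areas$fraction <- 7 # constant area
  expect_error(regress_std_on_area(std, areas), "constant")
  expect_error(regress_std_on_area(std[1:3, ], areas[1:3, ]), "5 aligned")
})

test_that("climate covariates explain STD with the right sign and strength", {
  set.seed(81)
  yrs <- 1959:2016
  map <- annual_series(yrs, 1480 + cumsum(rnorm(58, 0, 12)), label = "MAP")
  w <- enumerate_windows(1959, 2016, 20)
  map_mean <- windowed_mean(map, w)
  # STD driven negatively by long-term MAP
  std_vals <- 2 - 0.0008 * map_mean$mean + rnorm(nrow(w), 0, 0.01)
  std <- structure(
    cbind(w[, c("start_year", "end_year", "center_year")],
          data.frame(std = std_vals, n = 20,
                     normalized = std_vals / std_vals[1])),
    class = c("std_series", "data.frame"))
  tab <- explain_std_with_climate(std, list(MAP = map, MAT = NULL)[1],
                                  autocorr_correct = TRUE)
  expect_equal(tab$sign, -1)
  expect_gt(tab$r2, 0.8)
  expect_equal(tab$sig, "**")
  # correction strips shared smoothness, so corrected r2 must not exceed raw
  expect_lte(tab$r2_adj, tab$r2 + 0.05)

  # an orthogonal covariate explains nearly nothing
  set.seed(82)
  noise_cov <- annual_series(yrs, rnorm(58), label = "X")
  tab2 <- explain_std_with_climate(std, list(X = noise_cov),
                                   autocorr_correct = FALSE)
  expect_lt(tab2$r2, 0.15)
})

test_that("regional partition conserves totals and follows weights", {
  w <- enumerate_windows(2000, 2039, 20, step = 1)
  regions <- c("T.America", "T.Africa", "T.Asia")
  base <- data.frame(start_year = w$start_year, end_year = w$end_year)
  mk_area <- function(region, frac) {
    cbind(base, data.frame(region = region, band = "very_extreme+extreme",
                           fraction = frac))
  }
  areas <- rbind(
    mk_area("pantropic", 9 + 0.05 * seq_len(nrow(w))),
    mk_area("T.America", 3 + 0.05 * seq_len(nrow(w))),
    mk_area("T.Africa", rep(3, nrow(w))),
    mk_area("T.Asia", rep(3, nrow(w))))
  fit <- structure(list(slope_no_intercept = 0.14, slope = 0.14,
                        predictor = "very_extreme+extreme"),
                   class = "attribution_fit")
  periods <- list(c(2000, 2019), c(2020, 2039))

  # uniform weights, equal areas in period 1 -> near-equal thirds
  part <- partition_regions(fit, areas,
                            weights = c(T.America = 1, T.Africa = 1,
                                        T.Asia = 1),
                            periods = periods, regions = regions)
  pan <- attr(part, "pantropic")
  p1 <- part[part$period == "2000-2019", ]
  expect_equal(sum(p1$contribution), pan[["2000-2019"]], tolerance = 1e-10)
  p2 <- part[part$period == "2020-2039", ]
  expect_equal(sum(p2$contribution), pan[["2020-2039"]], tolerance = 1e-10)

  # doubling one region's weight raises its share, sum conserved
  part2 <- partition_regions(fit, areas,
                             weights = c(T.America = 2, T.Africa = 1,
                                         T.Asia = 1),
                             periods = periods, regions = regions)
  p1b <- part2[part2$period == "2000-2019", ]
  expect_gt(p1b$contribution[p1b$region == "T.America"],
            p1$contribution[p1$region == "T.America"])
  expect_lt(p1b$contribution[p1b$region == "T.Africa"],
            p1$contribution[p1$region == "T.Africa"])
  expect_equal(sum(p1b$contribution), pan[["2000-2019"]], tolerance = 1e-10)

  # only America's drought area grows: the inter-period change is hers
  ch <- function(p, r) {
    p$contribution[p$period == "2020-2039" & p$region == r] -
      p$contribution[p$period == "2000-2019" & p$region == r]
  }
  change_total <- sum(vapply(regions, ch, numeric(1), p = part))
  expect_gt(ch(part, "T.America") / change_total, 0.9)
})

test_that("uniform weights and equal areas split the prediction in thirds", {
  w <- enumerate_windows(2000, 2019, 20)
  base <- data.frame(start_year = w$start_year, end_year = w$end_year)
  areas <- do.call(rbind, lapply(
    c("pantropic", "T.America", "T.Africa", "T.Asia"),
    function(r) cbind(base, data.frame(
      region = r, band = "b",
      fraction = if (r == "pantropic") 9 else 3))))
  fit <- structure(list(slope_no_intercept = 0.14),
                   class = "attribution_fit")
  part <- partition_regions(fit, areas,
                            weights = c(T.America = 1, T.Africa = 1,
                                        T.Asia = 1),
                            periods = list(c(2000, 2019)))
  expect_equal(part$contribution, rep(0.14 * 9 / 3, 3))
})

test_that("sensitivity-STD relationship detects proportionality and nulls", {
  w <- enumerate_windows(1959, 2016, 20)
  set.seed(55)
  std_vals <- runif(nrow(w), 0.8, 1.4)
  std <- structure(
    cbind(w[, c("start_year", "end_year", "center_year")],
          data.frame(std = std_vals, n = 20,
                     normalized = std_vals / std_vals[1])),
    class = c("std_series", "data.frame"))
  gammas <- cbind(w[, c("start_year", "end_year", "center_year")],
                  data.frame(gamma_T = 4 * std_vals))
  r <- sensitivity_vs_std(gammas, std)
  expect_equal(r$r2, 1, tolerance = 1e-10)
  expect_equal(r$slope, 4, tolerance = 1e-10)

  # constant gamma with noisy STD: no significant relationship in >= 90%
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    gam2 <- gammas
    gam2$gamma_T <- 4 + rnorm(nrow(w), 0, 0.3)
    st2 <- std
    st2$std <- runif(nrow(w), 0.8, 1.4)
    r2 <- sensitivity_vs_std(gam2, st2)
    if (r2$p >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 43L) # ~5% nominal false positives
})

test_that("end-to-end synthetic run recovers the area-variability slope", {
  # drought epochs -> area series; CGR noise amplitude tied to area with a
  # known slope; regression through the origin recovers it within 2 SE
  for (s_true in c(0.05, 0.14, 0.30)) {
    n_years <- 200L
    n_months <- n_years * 12L
    third <- n_months %/% 3
    world <- small_drought_world(
      n_lat = 4, n_lon = 6, n_years = n_years, seed = 300 + round(100 * s_true),
      epochs = list(list(from = third + 1L, to = 2L * third,
                         multiplier = 0.75),
                    list(from = 2L * third + 1L, to = n_months,
                         multiplier = 0.55)))
    ct <- classify_drought(pixel_percentiles(world$grid))
    wins <- enumerate_windows(2000, 2000 + n_years - 1, 20, step = 20)
    area <- windowed_drought_area(ct, world$mask, wins)
    set.seed(400 + round(100 * s_true))
    vals <- unlist(lapply(seq_len(nrow(wins)), function(i) {
      rnorm(20, 0, s_true * area$fraction[i])
    }))
    cgr <- annual_series(2000:(2000 + n_years - 1), vals, label = "CGR")
    std <- std_windows(cgr, wins, detrend_within = FALSE)
    fit <- regress_std_on_area(std, area)
    expect_lt(abs(fit$slope_no_intercept - s_true),
              2 * fit$se_no_intercept)
  }
})
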