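test_that("noiseless synthetic CGR is recovered to machine precision", {
  sys <- noiseless_system(seed = 3L, gamma_T = 2, gamma_W = 0.01,
                          gamma_R = 0.05)
  fit <- fit_model("M1", sys$cgr, sys$climate)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(est[["MAT"]], 2, tolerance = 1e-10)
  expect_equal(est[["MAP"]], 0.01, tolerance = 1e-10)
  expect_equal(est[["RAD"]], 0.05, tolerance = 1e-10)
  expect_gt(fit$adj_r2, 0.999999)
})

test_that("VIF matches the auxiliary-regression definition and lm-based oracle", {
  # predictors orthogonal to each other and to the intercept: VIF exactly 1
  n <- 24
  base <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4]
  yrs <- 2000L + seq_len(n) - 1L
  preds <- list(MAT = annual_series(yrs, base[, 1]),
                MAP = annual_series(yrs, base[, 2]),
                RAD = annual_series(yrs, base[, 3]))
  cgr <- annual_series(yrs, base %*% c(1, 2, 3) + rnorm(n, 0, 0.1))
  fit <- fit_model("M1", cgr, preds, detrend = FALSE)
  expect_equal(unname(fit$vif), rep(1, 3), tolerance = 1e-8)

  # random correlated designs: agree with car::vif to 10 significant digits
  skip_if_not_installed("car")
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(15:30, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n) %*% (diag(k) + 0.5)
    y <- rnorm(n)
    yrs <- 1990L + seq_len(n) - 1L
    nm <- c("MAT", "MAP", "RAD", "TWS")[seq_len(k)]
    preds <- setNames(lapply(seq_len(k), function(j) {
      annual_series(yrs, X[, j])
    }), nm)
    model <- switch(as.character(k), "2" = NULL, "3" = "M1", "4" = NULL)
    if (is.null(model)) next
    fit <- fit_model(model, annual_series(yrs, y), preds, detrend = FALSE)
    df <- data.frame(y = y, X)
    names(df) <- c("y", nm)
    oracle <- car::vif(lm(y ~ ., data = df))
    expect_equal(fit$vif[nm], oracle[nm], tolerance = 1e-10)
  }
})

test_that("degenerate designs raise informative errors", {
  sys <- noiseless_system(seed = 4L)
  dup <- sys$climate
  dup$MAP <- dup$MAT # duplicated predictor column
  expect_error(fit_model("M1", sys$cgr, dup), "collinear")

  short <- enumerate_windows(1959, 1962, 4)
  expect_error(fit_model("M1", sys$cgr, sys$climate, window = short[1, ]),
               "at least")
  expect_error(fit_model("M3", sys$cgr, sys$climate["MAT"]), "requires")
})

test_that("AIC prefers the generating structure over an underfit model", {
  # M1 truth with all three predictors active; M7 omits MAP and RAD
  wins <- 0L
  for (s in 1:100) {
    climate <- gen_climate_series(flat_climate_spec(n_years = 30L, seed = s))
    cgr <- gen_cgr(climate, cgr_generator_spec(
      gamma_T = 2, gamma_W = 0.02, gamma_R = 0.5, noise_sd = 0.2, seed = s))
    f1 <- fit_model("M1", cgr, climate, vif = FALSE)
    f7 <- fit_model("M7", cgr, climate, vif = FALSE)
    if (f1$aic <= f7$aic) wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("AIC ranking is invariant to affine rescaling of predictors", {
  sys <- noiseless_system(seed = 8L)
  cgr <- sys$cgr
  cgr$value <- cgr$value + rnorm(length(cgr$value), 0, 0.3)
  a1 <- fit_model("M1", cgr, sys$climate)$aic
  a7 <- fit_model("M7", cgr, sys$climate)$aic
  scaled <- sys$climate
  scaled$MAT$value <- 100 * scaled$MAT$value - 3
  scaled$MAP$value <- scaled$MAP$value / 50 + 2
  b1 <- fit_model("M1", cgr, scaled)$aic
  b7 <- fit_model("M7", cgr, scaled)$aic
  expect_equal(a1, b1, tolerance = 1e-8)
  expect_equal(a7, b7, tolerance = 1e-8)
  expect_identical(a1 < a7, b1 < b7)
})

test_that("moving scan flags bad windows without aborting and tracks a flat truth", {
  climate <- gen_climate_series(flat_climate_spec(n_years = 58L, seed = 13L))
  cgr <- gen_cgr(climate, cgr_generator_spec(gamma_T = 5.49,
                                             noise_sd = 0.2, seed = 13L))
  # knock out most of one window's CGR
  cgr$value[3:17] <- NA
  w <- enumerate_windows(1959, 2016, 20)
  scan <- moving_sensitivity("M1", cgr, climate, w)
  expect_equal(nrow(scan), 39L)
  expect_true(any(!is.na(scan$error))) # early windows under-observed
  later <- scan[scan$start_year >= 1976, ]
  expect_true(all(is.na(later$error)))
  expect_equal(mean(later$gamma_T), 5.49, tolerance = 0.12) # relative tol
  expect_true(all(later$significant_05))
})

test_that("bootstrap SEs behave like the analytic OLS noise propagation", {
  sys <- noiseless_system(seed = 17L, gamma_T = 5.49, gamma_W = -0.003,
                          gamma_R = 0.05)
  cgr <- sys$cgr
  set.seed(99)
  cgr$value <- cgr$value + rnorm(length(cgr$value), 0, 0.2)

  b0 <- bootstrap_sensitivity("M1", cgr, sys$climate, reps = 50,
                              noise_sd = 0, seed = 1)
  expect_equal(b0$boot_se, rep(0, 4), tolerance = 1e-12)

  ses <- vapply(c(0.1, 0.2, 0.4), function(ns) {
    b <- bootstrap_sensitivity("M1", cgr, sys$climate, reps = 100,
                               noise_sd = ns, seed = 7)
    b$boot_se[b$term == "MAT"]
  }, numeric(1))
  expect_true(all(diff(ses) > 0))

  # analytic SE of gamma_T under y-noise sd 0.2: sd(coef) = 0.2 * sqrt(H H^T)
  fit <- fit_model("M1", cgr, sys$climate)
  b <- bootstrap_sensitivity("M1", cgr, sys$climate, reps = 400,
                             noise_sd = 0.2, seed = 3)
  # the analytic OLS coefficient SE uses the same design; residual sd ~ 0.2
  analytic <- fit$coefficients$se[fit$coefficients$term == "MAT"] *
    0.2 / sqrt(sum(fit$residuals^2) / (fit$n_effective - 4))
  boot_se <- b$boot_se[b$term == "MAT"]
  expect_equal(boot_se, analytic, tolerance = 0.25)

  expect_error(bootstrap_sensitivity("M1", cgr, sys$climate, reps = 1),
               "reps")
})

test_that("model comparison table summarises windows and flags low collinearity", {
  climate <- gen_climate_series(flat_climate_spec(n_years = 40L, seed = 23L))
  cgr <- gen_cgr(climate, cgr_generator_spec(noise_sd = 0.2, seed = 23L))
  w <- enumerate_windows(1959, 1998, 20)
  scans <- list(M1 = moving_sensitivity("M1", cgr, climate, w),
                M2 = moving_sensitivity("M2", cgr, climate, w),
                M7 = moving_sensitivity("M7", cgr, climate, w))
  tab <- model_comparison_table(scans)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$n_windows == nrow(w)))
  expect_true(tab$lowest_collinearity[tab$model == "M1"])
  expect_true(is.nan(tab$vif_mean[tab$model == "M7"]) ||
                is.na(tab$vif_mean[tab$model == "M7"]))

  one <- model_comparison_table(list(M1 = scans$M1[1, ]))
  expect_equal(one$adj_r2_sd, 0)
  expect_equal(one$aic_sd, 0)
})

test_that("generating model attains the lowest mean AIC across windows", {
  # M1 truth with a superfluous interaction in M2: averaging AIC over
  # independent (non-overlapping) windows separates the models far more
  # reliably than any single window does
  wins <- 0L
  w <- enumerate_windows(1959, 2458, 50, step = 50)
  for (s in 101:200) {
    climate <- gen_climate_series(flat_climate_spec(n_years = 500L, seed = s))
    cgr <- gen_cgr(climate, cgr_generator_spec(
      gamma_T = 5.49, gamma_W = -0.003, gamma_R = 0.05, gamma_i = 0,
      noise_sd = 0.2, seed = s))
    scans <- list(M1 = moving_sensitivity("M1", cgr, climate, w, vif = FALSE),
                  M2 = moving_sensitivity("M2", cgr, climate, w, vif = FALSE))
    tab <- model_comparison_table(scans)
    if (tab$aic_mean[tab$model == "M1"] <= tab$aic_mean[tab$model == "M2"]) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 90L)
})
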