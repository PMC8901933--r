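#' Predictor structure of the nine competing sensitivity models
#'
#' M1: dMAT + dMAP + dRAD; M2: M1 + z(dMAT*dMAP); M3: dMAT + dTWS + dRAD;
#' M4: dMAT + dMAPlag + dRAD; M5: M3 + z(dMAT*dTWS); M6: M4 +
#' z(dMAT*dMAPlag); M7: dMAT; M8: dTWS; M9: dMAPlag. Interaction terms
#' (written `A:B`) are products of anomalies, z-scored within the fitting
#' window before entering the regression.
#'
#' @return Named list of character vectors of predictor terms.
#' @export
model_terms <- function() {
  list(
    M1 = c("MAT", "MAP", "RAD"),
    M2 = c("MAT", "MAP", "RAD", "MAT:MAP"),
    M3 = c("MAT", "TWS", "RAD"),
    M4 = c("MAT", "MAPlag", "RAD"),
    M5 = c("MAT", "TWS", "RAD", "MAT:TWS"),
    M6 = c("MAT", "MAPlag", "RAD", "MAT:MAPlag"),
    M7 = "MAT",
    M8 = "TWS",
    M9 = "MAPlag"
  )
}

# Core OLS on an explicit design matrix (intercept included by caller).
# Returns coefficients, standard errors, two-sided p-values, fit stats.
# Errors on rank deficiency, naming the offending columns.
ols_fit <- function(X, y) {
  n <- length(y); k <- ncol(X)
  XtX <- crossprod(X)
  XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
  if (is.null(XtXinv)) {
    stop("singular design matrix; collinear predictors among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  coef <- drop(XtXinv %*% crossprod(X, y))
  names(coef) <- colnames(X)
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k)
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(X)
  tval <- coef / se
  p <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(coef = coef, se = se, p = p, residuals = res, rss = rss,
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k),
       n = n, k = k, sigma2 = sigma2)
}

# Build the design matrix (intercept + anomaly terms) for one model over a
# set of years. `predictors` holds raw annual series; anomalies are
# computed by detrending over exactly the years used (when detrend = TRUE).
build_design <- function(model_id, cgr, predictors, years,
                         detrend = TRUE) {
  terms <- model_terms()[[model_id]]
  if (is.null(terms)) stop("unknown model: ", model_id, call. = FALSE)
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(base_vars, names(predictors))
  if (length(miss)) {
    stop(model_id, " requires predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(predictors[base_vars], series_values, years = years)
  y <- series_values(cgr, years)
  ok <- !is.na(y) & !Reduce(`|`, lapply(vals, is.na))
  years_ok <- years[ok]
  y <- y[ok]
  vals <- lapply(vals, `[`, ok)
  anom <- if (detrend) {
    lapply(vals, function(v) detrend_vector(years_ok, v))
  } else vals
  y_an <- if (detrend) detrend_vector(years_ok, y) else y
  cols <- lapply(terms, function(tm) {
    pr <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(pr) == 1) return(anom[[pr]])
    v <- anom[[pr[1]]] * anom[[pr[2]]]
    s <- stats::sd(v)
    if (s == 0) stop("degenerate interaction term in ", model_id,
                     call. = FALSE)
    (v - mean(v)) / s # window-local z-score of the interaction
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", terms)
  list(X = X, y = y_an, years = years_ok)
}

#' Fit one sensitivity model on one window
#'
#' Ordinary least-squares fit (with intercept) of CGR anomalies on the
#' anomaly predictors of the requested model structure, over the window's
#' years minus exclusions and missing values. By default both CGR and the
#' predictors are detrended within the fitted years, matching the
#' window-local anomaly convention. Reports coefficient standard errors and
#' two-sided p-values, adjusted R2, the Gaussian-likelihood AIC
#' `n*log(RSS/n) + 2k` (k counting slopes, intercept and the variance), and
#' per-predictor variance inflation factors from auxiliary regressions.
#'
#' @param model_id One of `"M1"`..`"M9"` (see [model_terms()]).
#' @param cgr An [annual_series()] of CGR (raw; detrended internally) or
#'   precomputed anomalies (then set `detrend = FALSE`).
#' @param predictors Named list of raw predictor [annual_series()]
#'   (`MAT`, `MAP`, `RAD`, `TWS`, `MAPlag` as needed).
#' @param window One row of [enumerate_windows()] output, or `NULL` for the
#'   full shared range.
#' @param excluded_years Extra years to drop (used when `window` is `NULL`).
#' @param detrend Detrend response and predictors within the fitted years.
#' @param vif Compute variance inflation factors (skipped in tight loops).
#' @return An object of class `sensitivity_fit`.
#' @export
fit_model <- function(model_id, cgr, predictors, window = NULL,
                      excluded_years = integer(), detrend = TRUE,
                      vif = TRUE) {
  years <- if (is.null(window)) {
    setdiff(cgr$year, excluded_years)
  } else {
    window_years(window)
  }
  d <- build_design(model_id, cgr, predictors, years, detrend = detrend)
  n <- length(d$y); k <- ncol(d$X)
  if (n < k + 2) {
    stop(sprintf("%s needs at least %d observations, got %d",
                 model_id, k + 2, n), call. = FALSE)
  }
  fit <- ols_fit(d$X, d$y)
  k_aic <- k + 1L # slopes + intercept + residual variance
  aic <- n * log(fit$rss / n) + 2 * k_aic
  vifs <- if (vif && k > 2) vif_from_design(d$X) else NULL
  structure(
    list(model_id = model_id,
         window = if (is.null(window)) c(min(years), max(years))
                  else c(window$start_year, window$end_year),
         coefficients = data.frame(
           term = names(fit$coef), estimate = unname(fit$coef),
           se = unname(fit$se), p = unname(fit$p)),
         adj_r2 = fit$adj_r2, aic = aic, vif = vifs,
         n_effective = n, residuals = fit$residuals, years = d$years),
    class = "sensitivity_fit"
  )
}

# VIF_j = 1/(1 - R2_j) where R2_j comes from regressing predictor j on the
# other predictors (intercept included). Design includes the intercept in
# column 1; VIFs are reported for the remaining columns.
vif_from_design <- function(X) {
  pred <- X[, -1, drop = FALSE]
  k <- ncol(pred)
  if (k < 2) return(NULL)
  out <- vapply(seq_len(k), function(j) {
    aux <- ols_fit(cbind(1, pred[, -j, drop = FALSE]), pred[, j])
    1 / (1 - aux$r2)
  }, numeric(1))
  names(out) <- colnames(pred)
  out
}

#' @export
print.sensitivity_fit <- function(x, ...) {
  cat(sprintf("<sensitivity_fit> %s, window %d-%d, n = %d\n",
              x$model_id, x$window[1], x$window[2], x$n_effective))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("adj R2 = %.3f, AIC = %.2f%s\n", x$adj_r2, x$aic,
              if (!is.null(x$vif))
                paste0(", max VIF = ", signif(max(x$vif), 3)) else ""))
  invisible(x)
}

# Coefficient row for a named term, NA if absent.
fit_coef <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) return(c(estimate = NA_real_, se = NA_real_, p = NA_real_))
  with(fit$coefficients[i, ], c(estimate = estimate, se = se, p = p))
}

#' Moving-window sensitivity scan
#'
#' Fits one model on every window, dropping excluded years, and collects
#' the temperature and water coefficients with their significance. Windows
#' whose fit fails (e.g. too many missing years) are flagged and reported
#' as `NA` rows; the scan itself never aborts.
#'
#' @inheritParams fit_model
#' @param windows Data frame from [enumerate_windows()].
#' @return Data frame with one row per window: window bounds, `gamma_T`,
#'   `gamma_T_se`, `gamma_T_p`, `significant_05` (the p < 0.05 marker
#'   convention), the water coefficient columns, `adj_r2`, `aic`, `max_vif`,
#'   `n_effective` and `error`. The full fit objects are attached as the
#'   `"fits"` attribute.
#' @export
moving_sensitivity <- function(model_id, cgr, predictors, windows,
                               detrend = TRUE, vif = TRUE) {
  water_term <- intersect(model_terms()[[model_id]],
                          c("MAP", "TWS", "MAPlag"))[1]
  fits <- vector("list", nrow(windows))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    fit <- tryCatch(
      fit_model(model_id, cgr, predictors, window = w,
                detrend = detrend, vif = vif),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(
        start_year = w$start_year, end_year = w$end_year,
        center_year = w$center_year,
        gamma_T = NA_real_, gamma_T_se = NA_real_, gamma_T_p = NA_real_,
        significant_05 = NA,
        gamma_W = NA_real_, gamma_W_se = NA_real_, gamma_W_p = NA_real_,
        adj_r2 = NA_real_, aic = NA_real_, max_vif = NA_real_,
        n_effective = NA_integer_, error = conditionMessage(fit)))
    }
    fits[[i]] <<- fit
    gT <- fit_coef(fit, "MAT")
    gW <- if (is.na(water_term)) c(estimate = NA_real_, se = NA_real_,
                                   p = NA_real_)
          else fit_coef(fit, water_term)
    data.frame(
      start_year = w$start_year, end_year = w$end_year,
      center_year = w$center_year,
      gamma_T = gT[["estimate"]], gamma_T_se = gT[["se"]],
      gamma_T_p = gT[["p"]],
      significant_05 = !is.na(gT[["p"]]) && gT[["p"]] < 0.05,
      gamma_W = gW[["estimate"]], gamma_W_se = gW[["se"]],
      gamma_W_p = gW[["p"]],
      adj_r2 = fit$adj_r2, aic = fit$aic,
      max_vif = if (is.null(fit$vif)) NA_real_ else max(fit$vif),
      n_effective = fit$n_effective, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "model_id") <- model_id
  out
}

#' Bootstrap uncertainty of sensitivity coefficients
#'
#' Propagates CGR observational uncertainty into the fitted coefficients:
#' each replicate perturbs the raw CGR values with i.i.d. Gaussian noise
#' (default sd 0.2 PgC yr-1, the conventional CGR uncertainty), re-detrends
#' and refits; the bootstrap standard error is the standard deviation of
#' each coefficient across replicates (default 100), with percentile
#' intervals.
#'
#' @inheritParams fit_model
#' @param reps Number of replicates (>= 2).
#' @param noise_sd Perturbation standard deviation, PgC yr-1.
#' @param seed RNG seed.
#' @param probs Percentile interval bounds.
#' @return An object of class `bootstrap_result`: data frame `term`,
#'   `estimate`, `boot_se`, `lower`, `upper` plus attributes.
#' @export
bootstrap_sensitivity <- function(model_id, cgr, predictors, window = NULL,
                                  reps = 100L, noise_sd = 0.2, seed = 1L,
                                  excluded_years = integer(),
                                  detrend = TRUE,
                                  probs = c(0.025, 0.975)) {
  if (reps < 2) stop("reps must be >= 2 for a bootstrap SE", call. = FALSE)
  base <- fit_model(model_id, cgr, predictors, window = window,
                    excluded_years = excluded_years, detrend = detrend,
                    vif = FALSE)
  years <- base$years
  d <- build_design(model_id, cgr, predictors, years, detrend = detrend)
  X <- d$X
  H <- chol2inv(chol(crossprod(X))) %*% t(X) # k x n projector, reused
  y_raw <- series_values(cgr, years)
  set.seed(seed)
  noise <- matrix(stats::rnorm(length(years) * reps, 0, noise_sd),
                  ncol = reps)
  coefs <- apply(noise, 2, function(eps) {
    y <- y_raw + eps
    if (detrend) y <- detrend_vector(years, y)
    drop(H %*% y)
  })
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1)
  rownames(coefs) <- colnames(X)
  qs <- apply(coefs, 1, stats::quantile, probs = probs)
  out <- data.frame(
    term = colnames(X),
    estimate = base$coefficients$estimate,
    boot_se = apply(coefs, 1, stats::sd),
    lower = qs[1, ], upper = qs[2, ])
  rownames(out) <- NULL
  structure(out, class = c("bootstrap_result", "data.frame"),
            model_id = model_id, window = base$window, reps = reps,
            noise_sd = noise_sd, seed = seed)
}

#' Summarise model performance across windows
#'
#' Per model: mean and standard deviation of adjusted R2, AIC and max VIF
#' across the fitted windows, mirroring the convention of reporting
#' window-ensemble statistics as mean +/- one standard deviation. Flags the
#' multivariate models with the lowest mean collinearity.
#'
#' @param scans Named list of [moving_sensitivity()] results (names =
#'   model ids), or a single result.
#' @return Data frame with one row per model.
#' @export
model_comparison_table <- function(scans) {
  if (is.data.frame(scans)) {
    scans <- stats::setNames(list(scans), attr(scans, "model_id"))
  }
  rows <- lapply(names(scans), function(id) {
    s <- scans[[id]]
    ok <- is.na(s$error)
    sd0 <- function(x) if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else 0
    data.frame(
      model = id,
      n_windows = sum(ok),
      adj_r2_mean = mean(s$adj_r2, na.rm = TRUE),
      adj_r2_sd = sd0(s$adj_r2),
      aic_mean = mean(s$aic, na.rm = TRUE),
      aic_sd = sd0(s$aic),
      vif_mean = mean(s$max_vif, na.rm = TRUE),
      vif_sd = sd0(s$max_vif))
  })
  out <- do.call(rbind, rows)
  multi <- !is.na(out$vif_mean) & !is.nan(out$vif_mean)
  out$lowest_collinearity <- FALSE
  if (any(multi)) {
    out$lowest_collinearity[multi] <-
      rank(out$vif_mean[multi], ties.method = "min") <= 2
  }
  out
}
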