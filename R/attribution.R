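#' Windowed standard-deviation (STD) series
#'
#' The variability magnitude of an annual series: the sample standard
#' deviation within each moving window, by default of the within-window
#' linearly detrended values (a raw, undetrended variant is retained since
#' both conventions appear in practice). Excluded years are omitted. The
#' normalised variant divides every window by the first window's value.
#'
#' @param series An [annual_series()] (e.g. CGR or annual NEE).
#' @param windows Data frame from [enumerate_windows()].
#' @param detrend_within Detrend within each window before taking the SD.
#' @return Data frame of class `std_series`: `start_year`, `end_year`,
#'   `center_year`, `std`, `normalized`, `n`; attribute `label`.
#' @export
std_windows <- function(series, windows, detrend_within = TRUE) {
  stopifnot(inherits(series, "annual_series"))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    yrs <- window_years(windows[i, ])
    v <- series_values(series, yrs)
    ok <- !is.na(v)
    if (sum(ok) < 3) {
      stop(sprintf("window %d-%d has fewer than 3 non-missing values",
                   windows$start_year[i], windows$end_year[i]),
           call. = FALSE)
    }
    vv <- if (detrend_within) detrend_vector(yrs[ok], v[ok]) else v[ok]
    data.frame(start_year = windows$start_year[i],
               end_year = windows$end_year[i],
               center_year = windows$center_year[i],
               std = stats::sd(vv), n = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (out$std[1] == 0) {
    stop("first-window STD is zero; normalisation undefined", call. = FALSE)
  }
  out$normalized <- out$std / out$std[1]
  structure(out, class = c("std_series", "data.frame"),
            label = series$label, detrended = detrend_within)
}

# align two windowed data frames on (start_year, end_year)
align_windows <- function(a, b) {
  key_a <- paste(a$start_year, a$end_year)
  key_b <- paste(b$start_year, b$end_year)
  i <- match(key_a, key_b)
  ok <- !is.na(i)
  list(a = a[ok, , drop = FALSE], b = b[i[ok], , drop = FALSE])
}

#' Regress windowed STD on drought-affected area
#'
#' Ordinary least-squares fit of the windowed STD series on the windowed
#' drought-area fraction, reported both with and without an intercept (the
#' without-intercept slope encodes that zero drought area predicts zero
#' drought-driven variability and is the one used for partitioning).
#' Optionally the pair is passed through the Cochrane-Orcutt adjusted
#' regression to control for the serial correlation that the moving window
#' induces.
#'
#' @param std A [std_windows()] result.
#' @param area A [windowed_drought_area()] result aligned on windows.
#' @param autocorr_correct Also compute the autocorrelation-adjusted fit.
#' @return List of class `attribution_fit`: `slope` / `intercept` / `r2` /
#'   `p` (with intercept), `slope_no_intercept` (+ se, p), optional
#'   `adjusted` ([adjusted_regression()] result), `n`, `predictor`.
#' @export
regress_std_on_area <- function(std, area, autocorr_correct = FALSE) {
  al <- align_windows(as.data.frame(std), area)
  n <- nrow(al$a)
  if (n < 5) stop("fewer than 5 aligned windows", call. = FALSE)
  y <- al$a$std
  x <- al$b$fraction
  if (stats::sd(x) == 0) {
    stop("drought-area fraction is constant across windows", call. = FALSE)
  }
  with_i <- ols_fit(cbind(1, area = x), y)
  no_i <- ols_fit(cbind(area = x), y)
  adj <- if (autocorr_correct) adjusted_regression(x, y) else NULL
  structure(
    list(slope = with_i$coef[["area"]], se = with_i$se[["area"]],
         intercept = with_i$coef[[1]], r2 = with_i$r2,
         p = with_i$p[["area"]],
         slope_no_intercept = no_i$coef[["area"]],
         se_no_intercept = no_i$se[["area"]],
         p_no_intercept = no_i$p[["area"]],
         adjusted = adj, n = n,
         predictor = al$b$band[1]),
    class = "attribution_fit"
  )
}

#' @export
print.attribution_fit <- function(x, ...) {
  cat(sprintf(
    "<attribution_fit> STD ~ area[%s], n = %d windows\n", x$predictor, x$n))
  cat(sprintf("  with intercept:    slope = %.4f PgC yr-1 %%-1 (se %.4f), r2 = %.3f, p = %.3g\n",
              x$slope, x$se, x$r2, x$p))
  cat(sprintf("  without intercept: slope = %.4f PgC yr-1 %%-1 (se %.4f)\n",
              x$slope_no_intercept, x$se_no_intercept))
  if (!is.null(x$adjusted)) {
    cat(sprintf("  autocorrelation-adjusted: slope = %.4f, r2 = %.3f, p = %.3g\n",
                x$adjusted$slope, x$adjusted$r2, x$adjusted$p))
  }
  invisible(x)
}

#' Windowed mean of an annual series
#'
#' The long-term (window-mean) covariates used to explain STD, e.g. 20-year
#' mean precipitation or temperature.
#'
#' @param series An [annual_series()].
#' @param windows Data frame from [enumerate_windows()].
#' @return Data frame `start_year`, `end_year`, `center_year`, `mean`.
#' @export
windowed_mean <- function(series, windows) {
  rows <- vapply(seq_len(nrow(windows)), function(i) {
    v <- series_values(series, window_years(windows[i, ]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(start_year = windows$start_year, end_year = windows$end_year,
             center_year = windows$center_year, mean = rows)
}

#' Explain STD with long-term climate covariates
#'
#' Univariate regressions of the windowed STD series on each windowed-mean
#' climate covariate (e.g. 20-year mean TWS, SWC, MAP, VPD, MAT): reports
#' r2, slope sign and p, at the p < 0.1 / p < 0.01 significance tiers, and
#' optionally the autocorrelation-corrected variant of each fit.
#'
#' @param std A [std_windows()] result.
#' @param covariates Named list of [annual_series()]; each is reduced with
#'   [windowed_mean()] over the STD windows.
#' @param autocorr_correct Add corrected columns via
#'   [adjusted_regression()].
#' @return Data frame, one row per covariate: `covariate`, `r2`, `sign`,
#'   `slope`, `p`, `sig` (`"**"`, `"*"` or `""`), and when corrected
#'   `r2_adj`, `p_adj`, `sig_adj`.
#' @export
explain_std_with_climate <- function(std, covariates,
                                     autocorr_correct = TRUE) {
  sdf <- as.data.frame(std)
  windows <- sdf[, c("start_year", "end_year", "center_year")]
  windows$excluded <- replicate(nrow(windows), integer(), simplify = FALSE)
  tiers <- function(p) if (p < 0.01) "**" else if (p < 0.1) "*" else ""
  rows <- lapply(names(covariates), function(nm) {
    cm <- windowed_mean(covariates[[nm]], windows)
    fit <- ols_fit(cbind(1, x = cm$mean), sdf$std)
    row <- data.frame(covariate = nm, r2 = fit$r2,
                      sign = sign(fit$coef[["x"]]),
                      slope = fit$coef[["x"]], p = fit$p[["x"]],
                      sig = tiers(fit$p[["x"]]))
    if (autocorr_correct) {
      adj <- adjusted_regression(cm$mean, sdf$std)
      row$r2_adj <- adj$r2
      row$p_adj <- adj$p
      row$sig_adj <- tiers(adj$p)
    }
    row
  })
  do.call(rbind, rows)
}

#' Mean regional NEE-magnitude weights
#'
#' The spatial weight of each region: the mean absolute NEE weight over the
#' region's vegetated pixels (the magnitude of land-atmosphere exchange;
#' configurable to the signed mean).
#'
#' @param mask A [region_mask()] carrying `nee_weight`.
#' @param regions Character vector of region labels.
#' @param use_abs Use `|NEE|` (default) or the signed mean.
#' @return Named numeric vector of weights.
#' @export
region_weights <- function(mask, regions, use_abs = TRUE) {
  if (is.null(mask$nee_weight)) {
    stop("mask has no NEE weight map", call. = FALSE)
  }
  w <- vapply(regions, function(r) {
    sel <- region_selector(mask, r)
    v <- mask$nee_weight[sel]
    if (use_abs) mean(abs(v), na.rm = TRUE) else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (all(w == 0)) stop("zero total regional weight", call. = FALSE)
  w
}

#' Partition predicted STD into regional contributions
#'
#' Time-for-space substitution: the temporally estimated (no-intercept)
#' STD-versus-area slope predicts the pantropic drought-driven STD in each
#' period, which is then split across regions in proportion to
#' `w_r * A_r`, where `A_r` is the region's mean drought-area fraction over
#' the period's windows and `w_r` its mean NEE-magnitude weight. For every
#' window the regional shares sum to one, so the regional contributions sum
#' exactly to the pantropic prediction. The uncertainty of each
#' contribution is the standard deviation of its per-window values within
#' the period (propagated from the within-period variability of the
#' drought-area fractions).
#'
#' @param fit An [regress_std_on_area()] result (its
#'   `slope_no_intercept` is used).
#' @param areas Long data frame from [regional_breakdown()] (or
#'   rbind-ed [windowed_drought_area()] calls) containing a `pantropic` row
#'   set plus the regions to partition, all with pantropic denominators.
#' @param weights Named weights from [region_weights()], or a named numeric
#'   vector; names must cover the regions present in `areas`.
#' @param periods List of `c(start_year, end_year)` periods; a window
#'   belongs to a period when it lies entirely inside it.
#' @param regions Regions to partition over (default the three continents).
#' @return Data frame of class `partition_result`: `period`, `region`,
#'   `contribution` (PgC yr-1), `uncertainty`, `mean_area`; pantropic
#'   predictions attached as attribute `pantropic`.
#' @export
partition_regions <- function(fit, areas, weights,
                              periods = list(c(1960, 1979), c(1980, 1999),
                                             c(1997, 2016)),
                              regions = c("T.America", "T.Africa",
                                          "T.Asia")) {
  stopifnot(inherits(fit, "attribution_fit"))
  slope <- fit$slope_no_intercept
  miss <- setdiff(regions, names(weights))
  if (length(miss)) {
    stop("weights missing for region(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pan <- areas[areas$region == "pantropic", ]
  if (!nrow(pan)) stop("areas must include a pantropic series", call. = FALSE)
  out <- list()
  pan_pred <- list()
  for (p in periods) {
    label <- sprintf("%d-%d", p[1], p[2])
    keep <- pan$start_year >= p[1] & pan$end_year <= p[2]
    wins <- pan[keep, c("start_year", "end_year")]
    if (!nrow(wins)) {
      stop("no windows inside period ", label, call. = FALSE)
    }
    key <- paste(wins$start_year, wins$end_year)
    A <- sapply(regions, function(r) {
      ar <- areas[areas$region == r, ]
      ar$fraction[match(key, paste(ar$start_year, ar$end_year))]
    })
    A <- matrix(A, nrow = nrow(wins),
                dimnames = list(NULL, regions)) # windows x regions
    if (anyNA(A)) {
      stop("regional areas do not cover the period ", label, call. = FALSE)
    }
    A_pan <- pan$fraction[keep]
    wA <- sweep(A, 2, weights[regions], `*`)
    tot <- rowSums(wA)
    if (any(tot == 0)) stop("zero total weight in period ", label,
                            call. = FALSE)
    shares <- wA / tot
    contrib <- shares * (slope * A_pan) # windows x regions
    pan_pred[[label]] <- slope * mean(A_pan)
    out[[label]] <- data.frame(
      period = label, region = regions,
      contribution = colMeans(contrib),
      uncertainty = if (nrow(contrib) > 1) apply(contrib, 2, stats::sd)
                    else NA_real_,
      mean_area = colMeans(A))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  structure(res, class = c("partition_result", "data.frame"),
            pantropic = unlist(pan_pred), slope = slope)
}

#' Relate fitted climate sensitivities to STD
#'
#' Ordinary regression of a windowed sensitivity trajectory (gamma_T or
#' gamma_W from [moving_sensitivity()]) on the windowed STD series, with an
#' optional autocorrelation-robust variant: the mechanism by which changes
#' in variability magnitude manifest as apparent sensitivity changes.
#'
#' @param gammas A [moving_sensitivity()] result.
#' @param std A [std_windows()] result.
#' @param coefficient `"gamma_T"` or `"gamma_W"`.
#' @param autocorr_correct Also fit the adjusted regression.
#' @return List: `slope`, `r2`, `p`, `n`, optional `adjusted`.
#' @export
sensitivity_vs_std <- function(gammas, std, coefficient = "gamma_T",
                               autocorr_correct = FALSE) {
  al <- align_windows(gammas, as.data.frame(std))
  g <- al$a[[coefficient]]
  s <- al$b$std
  ok <- !is.na(g) & !is.na(s)
  if (sum(ok) < 5) stop("fewer than 5 aligned windows", call. = FALSE)
  fit <- ols_fit(cbind(1, std = s[ok]), g[ok])
  list(slope = fit$coef[["std"]], se = fit$se[["std"]], r2 = fit$r2,
       p = fit$p[["std"]], n = sum(ok),
       adjusted = if (autocorr_correct) adjusted_regression(s[ok], g[ok])
                  else NULL)
}
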