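#' Durbin-Watson statistic
#'
#' `DW = sum_{i=2..n} (e_i - e_{i-1})^2 / sum_{i=1..n} e_i^2`, on the
#' residuals of a regression. DW lies in [0, 4]: 0 indicates perfect
#' positive lag-1 autocorrelation, 2 none, 4 negative.
#'
#' @param residuals Numeric residual vector, length >= 2, not all zero.
#' @return The DW statistic.
#' @examples
#' durbin_watson(c(1, -1, 1, -1)) # 3
#' @export
durbin_watson <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 2) stop("need n >= 2 residuals", call. = FALSE)
  denom <- sum(residuals^2)
  if (denom == 0) {
    stop("Durbin-Watson undefined for all-zero residuals", call. = FALSE)
  }
  sum(diff(residuals)^2) / denom
}

#' Lag-1 autoregressive coefficient of residuals
#'
#' Estimates rho in the AR(1) residual model `e_i = rho * e_{i-1} + r_i` by
#' ordinary least squares of `e_i` on `e_{i-1}` without intercept:
#' `rho = sum(e_i * e_{i-1}) / sum(e_{i-1}^2)`.
#'
#' @param residuals Numeric residual vector, length >= 3.
#' @return Estimated rho.
#' @export
estimate_rho <- function(residuals) {
  e <- as.numeric(residuals)
  n <- length(e)
  if (n < 3) stop("need n >= 3 residuals", call. = FALSE)
  lag <- e[-n]
  if (sum(lag^2) == 0) {
    stop("zero-variance lagged residuals", call. = FALSE)
  }
  sum(e[-1] * lag) / sum(lag^2)
}

#' Cochrane-Orcutt adjustment of a series
#'
#' Removes AR(1) structure by the quasi-difference
#' `y_adj_i = y_i - rho * y_{i-1}`; the output is one element shorter than
#' the input. A single pass is applied (no iteration to convergence).
#'
#' @param y Numeric vector or [annual_series()].
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @return Adjusted numeric vector (or annual series dropping the first
#'   year) of length `n - 1`.
#' @export
cochrane_orcutt <- function(y, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (inherits(y, "annual_series")) {
    v <- y$value
    if (length(v) < 2) stop("need n >= 2", call. = FALSE)
    return(annual_series(y$year[-1], v[-1] - rho * v[-length(v)],
                         units = y$units,
                         label = paste0(y$label, "_adj")))
  }
  v <- as.numeric(y)
  if (length(v) < 2) stop("need n >= 2", call. = FALSE)
  v[-1] - rho * v[-length(v)]
}

# residuals of an OLS linear fit against observation index
trend_residuals <- function(y) {
  detrend_vector(seq_along(y), y)
}

#' AR diagnostics of a series' trend residuals
#'
#' Convenience bundle: fits a linear trend against time, then reports the
#' lag-1 rho of the residuals, their Durbin-Watson statistic and n.
#'
#' @param y Numeric vector or [annual_series()].
#' @return List of class `ar_diagnostics`: `rho`, `dw`, `n`, `residuals`.
#' @export
ar_diagnostics <- function(y) {
  v <- if (inherits(y, "annual_series")) y$value else as.numeric(y)
  v <- v[!is.na(v)]
  e <- trend_residuals(v)
  structure(list(rho = estimate_rho(e), dw = durbin_watson(e),
                 n = length(e), residuals = e),
            class = "ar_diagnostics")
}

#' @export
print.ar_diagnostics <- function(x, ...) {
  cat(sprintf("<ar_diagnostics> n = %d, rho = %.3f, DW = %.3f\n",
              x$n, x$rho, x$dw))
  invisible(x)
}

#' Autocorrelation-corrected regression of y on x
#'
#' Both variables are adjusted for their own AR(1) structure before the
#' regression: each series' lag-1 rho is estimated from the residuals of its
#' linear trend against time, the raw series is quasi-differenced
#' (`y_adj_i = y_i - rho_y * y_{i-1}`, similarly for x), and ordinary least
#' squares of adjusted y on adjusted x is reported, alongside the
#' unadjusted fit. Significance is flagged at the p < 0.1 and p < 0.01
#' tiers. A `shared_rho` variant adjusts both series with the mean of the
#' two rho estimates.
#'
#' @param x,y Numeric vectors or [annual_series()] sharing an index.
#' @param shared_rho Use one common rho (mean of the two) for both series.
#' @return List of class `adjusted_regression`: slopes, intercepts, r2 and
#'   p for the adjusted and unadjusted fits, the rho estimates, and
#'   Durbin-Watson statistics of the y trend residuals before and after
#'   adjustment.
#' @export
adjusted_regression <- function(x, y, shared_rho = FALSE) {
  xv <- if (inherits(x, "annual_series")) x$value else as.numeric(x)
  yv <- if (inherits(y, "annual_series")) y$value else as.numeric(y)
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 5) stop("need n >= 5 paired observations", call. = FALSE)
  rho_x <- estimate_rho(trend_residuals(xv))
  rho_y <- estimate_rho(trend_residuals(yv))
  if (shared_rho) rho_x <- rho_y <- mean(c(rho_x, rho_y))
  if (abs(rho_x) >= 1 || abs(rho_y) >= 1) {
    stop("estimated |rho| >= 1; series unsuitable for quasi-differencing",
         call. = FALSE)
  }
  x_adj <- cochrane_orcutt(xv, rho_x)
  y_adj <- cochrane_orcutt(yv, rho_y)
  raw <- ols_fit(cbind(1, x = xv), yv)
  adj <- ols_fit(cbind(1, x = x_adj), y_adj)
  dw_before <- durbin_watson(trend_residuals(yv))
  dw_after <- durbin_watson(trend_residuals(y_adj))
  structure(
    list(slope = adj$coef[["x"]], intercept = adj$coef[[1]],
         se = adj$se[["x"]], r2 = adj$r2, p = adj$p[["x"]],
         slope_raw = raw$coef[["x"]], r2_raw = raw$r2,
         p_raw = raw$p[["x"]], se_raw = raw$se[["x"]],
         rho_x = rho_x, rho_y = rho_y,
         dw_before = dw_before, dw_after = dw_after, n = n,
         sig_10 = adj$p[["x"]] < 0.1, sig_01 = adj$p[["x"]] < 0.01),
    class = "adjusted_regression"
  )
}

#' @export
print.adjusted_regression <- function(x, ...) {
  star <- if (x$sig_01) "**" else if (x$sig_10) "*" else ""
  cat(sprintf(
    "<adjusted_regression> n = %d, rho(x) = %.2f, rho(y) = %.2f\n",
    x$n, x$rho_x, x$rho_y))
  cat(sprintf("  adjusted:   slope = %.4g, r2 = %.3f, p = %.3g%s\n",
              x$slope, x$r2, x$p, star))
  cat(sprintf("  unadjusted: slope = %.4g, r2 = %.3f, p = %.3g\n",
              x$slope_raw, x$r2_raw, x$p_raw))
  cat(sprintf("  DW of y trend residuals: %.2f before, %.2f after\n",
              x$dw_before, x$dw_after))
  invisible(x)
}

#' Enumerate independent short segments of a year span
#'
#' Partitions a span into consecutive non-overlapping segments of
#' `segment_length` years; when the span is not a multiple of the length,
#' the final segment is anchored at the last year and overlaps its
#' predecessor by the remainder (a 58-year span with 5-year segments gives
#' twelve segments, the last overlapping by 2 years).
#'
#' @param start_year,end_year Inclusive span.
#' @param segment_length Segment length in years.
#' @return Data frame `start_year`, `end_year`, `overlap` (years shared
#'   with the previous segment).
#' @export
enumerate_segments <- function(start_year, end_year, segment_length = 5L) {
  span <- end_year - start_year + 1L
  if (span < segment_length) {
    stop("span shorter than segment length", call. = FALSE)
  }
  n_full <- span %/% segment_length
  starts <- start_year + (seq_len(n_full) - 1L) * segment_length
  ends <- starts + segment_length - 1L
  overlap <- rep(0L, n_full)
  if (span %% segment_length != 0L) {
    starts <- c(starts, end_year - segment_length + 1L)
    overlap <- c(overlap, ends[n_full] - starts[n_full + 1L] + 1L)
    ends <- c(ends, end_year)
  }
  data.frame(start_year = starts, end_year = ends, overlap = overlap)
}

#' Independent 5-year-segment robustness analysis
#'
#' Recomputes the temperature and water sensitivities, the CGR standard
#' deviation and (optionally) the drought-affected area on short
#' non-overlapping segments, giving estimates free of the moving-window
#' autocorrelation. Sensitivities use univariate fits (CGR on MAT for
#' gamma_T, CGR on the water series for gamma_W): a 5-point segment cannot
#' support the full multivariate model. Segments with fewer than 4 usable
#' years are flagged missing.
#'
#' @param cgr An [annual_series()] of CGR.
#' @param predictors Named list with at least `MAT` and one of
#'   `MAP`/`TWS`/`MAPlag`.
#' @param segment_length Segment length in years (default 5).
#' @param excluded_years Years dropped from fits.
#' @param area Optional drought-area data frame (`start_year`, `end_year`,
#'   `fraction`) evaluated on the same segments.
#' @return Data frame with one row per segment: `gamma_T`, `gamma_W`,
#'   `std_cgr`, optional `area_fraction`, and `n`.
#' @export
segment_analysis <- function(cgr, predictors, segment_length = 5L,
                             excluded_years = integer(), area = NULL) {
  segs <- enumerate_segments(min(cgr$year), max(cgr$year), segment_length)
  water <- intersect(c("MAP", "TWS", "MAPlag"), names(predictors))[1]
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    yrs <- setdiff(seq(segs$start_year[i], segs$end_year[i]),
                   excluded_years)
    y <- series_values(cgr, yrs)
    tv <- series_values(predictors$MAT, yrs)
    wv <- if (!is.na(water)) series_values(predictors[[water]], yrs)
          else rep(NA_real_, length(yrs))
    ok <- !is.na(y) & !is.na(tv)
    if (sum(ok) < 4) {
      return(data.frame(start_year = segs$start_year[i],
                        end_year = segs$end_year[i],
                        overlap = segs$overlap[i],
                        gamma_T = NA_real_, gamma_W = NA_real_,
                        std_cgr = NA_real_, n = sum(ok)))
    }
    dy <- detrend_vector(yrs[ok], y[ok])
    dt <- detrend_vector(yrs[ok], tv[ok])
    gT <- ols_fit(cbind(1, MAT = dt), dy)$coef[["MAT"]]
    gW <- NA_real_
    okw <- ok & !is.na(wv)
    if (sum(okw) >= 4) {
      dyw <- detrend_vector(yrs[okw], y[okw])
      dw <- detrend_vector(yrs[okw], wv[okw])
      gW <- ols_fit(cbind(1, W = dw), dyw)$coef[["W"]]
    }
    data.frame(start_year = segs$start_year[i], end_year = segs$end_year[i],
               overlap = segs$overlap[i],
               gamma_T = gT, gamma_W = gW, std_cgr = stats::sd(dy),
               n = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (!is.null(area)) {
    out$area_fraction <- area$fraction[
      match(paste(out$start_year, out$end_year),
            paste(area$start_year, area$end_year))]
  }
  out
}
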