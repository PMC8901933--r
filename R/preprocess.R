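#' Convert an annual CO2 concentration series to CGR
#'
#' The atmospheric CO2 growth rate (CGR) for year t is the first difference
#' of the annual global mean concentration, converted from ppm to carbon
#' mass with the standard atmospheric conversion factor 2.124 GtC per ppm.
#' The first year has no difference and is absent from the output; a gap in
#' the concentration record leaves the year after the gap flagged missing.
#'
#' @param co2 An [annual_series()] of CO2 concentration in ppm.
#' @return An [annual_series()] of CGR in PgC yr-1.
#' @examples
#' co2 <- annual_series(2000:2001, c(400, 401), units = "ppm")
#' cgr_from_co2(co2)$value # 2.124
#' @export
cgr_from_co2 <- function(co2) {
  stopifnot(inherits(co2, "annual_series"))
  if (length(co2$year) < 2) {
    stop("need at least 2 years of CO2 concentration", call. = FALSE)
  }
  n <- length(co2$year)
  annual_series(co2$year[-1], diff(co2$value) * 2.124,
                units = "PgC yr-1", label = "CGR")
}

# Linear-trend residuals of values against x, NA-safe: NA in, NA out.
# Requires >= 3 non-missing points. Closed-form OLS keeps this exact.
detrend_vector <- function(x, values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) {
    stop("need at least 3 non-missing values to detrend", call. = FALSE)
  }
  xo <- x[ok]; yo <- values[ok]
  b <- sum((xo - mean(xo)) * (yo - mean(yo))) / sum((xo - mean(xo))^2)
  a <- mean(yo) - b * mean(xo)
  out <- values - (a + b * x)
  out
}

#' Linear-trend anomalies of an annual series
#'
#' Anomalies are the departures from the ordinary least-squares linear trend
#' line fitted against calendar year, over either the full series or a
#' stated year range. Years outside the range are dropped; missing values
#' stay missing.
#'
#' @param series An [annual_series()].
#' @param range Optional `c(start_year, end_year)`; default full series.
#' @return An [annual_series()] of anomalies (same units).
#' @export
detrend <- function(series, range = NULL) {
  stopifnot(inherits(series, "annual_series"))
  keep <- if (is.null(range)) rep(TRUE, length(series$year))
          else series$year >= range[1] & series$year <= range[2]
  yr <- series$year[keep]
  val <- detrend_vector(yr, series$value[keep])
  annual_series(yr, val, units = series$units,
                label = paste0("d", series$label))
}

#' Area-weighted tropical annual aggregate of a monthly grid
#'
#' For each calendar year, aggregates the grid months to a per-pixel annual
#' value (mean or total of the 12 months), then averages over vegetated
#' pixels with cos-latitude area weights, renormalising the weights over
#' pixels that have data. Years in which every vegetated pixel is missing
#' are flagged missing.
#'
#' @param grid A [monthly_grid()].
#' @param mask A [region_mask()] aligned with the grid.
#' @param statistic `"mean"` (e.g. temperature) or `"total"` (e.g. annual
#'   precipitation): the within-year, per-pixel aggregation.
#' @param label,units Metadata for the returned series.
#' @return An [annual_series()].
#' @export
tropical_annual_mean <- function(grid, mask, statistic = c("mean", "total"),
                                 label = "", units = grid$units) {
  statistic <- match.arg(statistic)
  check_alignment(grid, mask)
  veg <- mask$vegetated
  if (!any(veg)) stop("no vegetated pixel in mask", call. = FALSE)
  years <- unique(grid$months$year)
  w <- mask$area * veg
  npix <- length(veg)
  vmat <- matrix(grid$values, nrow = npix) # pixels x months
  out <- vapply(years, function(y) {
    mi <- which(grid$months$year == y)
    px <- if (statistic == "mean") rowMeans(vmat[, mi, drop = FALSE])
          else rowSums(vmat[, mi, drop = FALSE])
    ok <- !is.na(px) & as.vector(veg)
    if (!any(ok)) return(NA_real_)
    sum(px[ok] * as.vector(w)[ok]) / sum(as.vector(w)[ok])
  }, numeric(1))
  annual_series(years, out, units = units, label = label)
}

#' Area-weighted tropical monthly mean series of a grid
#'
#' @param grid A [monthly_grid()].
#' @param mask A [region_mask()].
#' @return Data frame `year, month, value` of the cos-latitude-weighted mean
#'   over vegetated pixels.
#' @export
tropical_monthly_series <- function(grid, mask) {
  check_alignment(grid, mask)
  veg <- as.vector(mask$vegetated)
  w <- as.vector(mask$area)[veg]
  vmat <- matrix(grid$values, nrow = length(veg))[veg, , drop = FALSE]
  val <- apply(vmat, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    sum(col[ok] * w[ok]) / sum(w[ok])
  })
  cbind(grid$months, data.frame(value = val))
}

check_alignment <- function(grid, mask) {
  if (!isTRUE(all.equal(grid$lat, mask$lat)) ||
      !isTRUE(all.equal(grid$lon, mask$lon))) {
    stop("grid and mask are not aligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Lagged annual precipitation (MAPlag)
#'
#' Aggregates monthly precipitation into annual values over a 12-month
#' window shifted `lag_months` back from the calendar year end: with the
#' default lag of 4, the value for year Y covers September of Y-1 through
#' August of Y. Years whose window extends before the record start are
#' flagged missing.
#'
#' @param monthly Data frame `year, month, value` (e.g. from
#'   [tropical_monthly_series()]).
#' @param lag_months Backward shift in months (0 = calendar year).
#' @param statistic `"total"` (mm yr-1, default) or `"mean"`.
#' @return An [annual_series()] labelled `MAPlag`.
#' @export
lagged_annual_precip <- function(monthly, lag_months = 4,
                                 statistic = c("total", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("year", "month", "value") %in% names(monthly)))
  mk <- monthly$year * 12L + (monthly$month - 1L)
  if (is.unsorted(mk, strictly = TRUE)) {
    o <- order(mk); monthly <- monthly[o, ]; mk <- mk[o]
  }
  years <- sort(unique(monthly$year))
  out <- vapply(years, function(y) {
    # window ends at month 12 - lag of year y, spans 12 months
    end_key <- y * 12L + (12L - lag_months - 1L)
    keys <- seq(end_key - 11L, end_key)
    idx <- match(keys, mk)
    if (anyNA(idx)) return(NA_real_)
    v <- monthly$value[idx]
    if (anyNA(v)) return(NA_real_)
    if (statistic == "total") sum(v) else mean(v)
  }, numeric(1))
  annual_series(years, out,
                units = if (statistic == "total") "mm yr-1" else "mm month-1",
                label = "MAPlag")
}

#' Enumerate moving analysis windows
#'
#' Sliding windows of a fixed length (default the study's 20 years) at a
#' given step over a year range. Each window records the subset of globally
#' excluded years (default none) that fall inside it; excluded years are
#' dropped from fits but windows keep their nominal span.
#'
#' @param start_year,end_year Inclusive year range.
#' @param length Window length in years (>= 3).
#' @param step Step between window starts.
#' @param excluded_years Years to exclude from fitting (e.g. 1991:1993, the
#'   Pinatubo-perturbed years).
#' @return Data frame with columns `start_year`, `end_year`, `center_year`
#'   and a list column `excluded`.
#' @examples
#' w <- enumerate_windows(1959, 2016, 20)
#' nrow(w) # 39
#' @export
enumerate_windows <- function(start_year, end_year, length = 20L, step = 1L,
                              excluded_years = integer()) {
  if (length < 3) stop("window length must be >= 3", call. = FALSE)
  span <- end_year - start_year + 1L
  if (span < length) {
    stop("year range shorter than window length", call. = FALSE)
  }
  starts <- seq(start_year, end_year - length + 1L, by = step)
  w <- data.frame(start_year = starts, end_year = starts + length - 1L)
  w$center_year <- (w$start_year + w$end_year) / 2
  w$excluded <- lapply(seq_len(nrow(w)), function(i) {
    intersect(excluded_years, seq(w$start_year[i], w$end_year[i]))
  })
  w
}

# Years used for fitting inside one window: the window span minus
# excluded years.
window_years <- function(window) {
  yrs <- seq(window$start_year, window$end_year)
  excl <- window$excluded
  if (is.list(excl)) excl <- excl[[1]]
  setdiff(yrs, excl)
}
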