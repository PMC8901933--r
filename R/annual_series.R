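#' Annual time series with units
#'
#' A calendar-year-indexed numeric series. Years are strictly increasing and
#' contiguous; missing values are carried explicitly as `NA`, never dropped.
#' This is the common currency of the package: CGR in PgC yr-1, tropical mean
#' annual temperature in deg C, annual precipitation in mm yr-1, and so on.
#'
#' @param years Integer calendar years, strictly increasing.
#' @param values Numeric values, same length as `years`; `NA` marks missing.
#' @param units Unit label, e.g. `"PgC yr-1"`.
#' @param label Variable label, e.g. `"CGR"`.
#' @return An object of class `annual_series`: a list with elements `year`,
#'   `value`, `units`, `label`.
#' @examples
#' s <- annual_series(2000:2004, c(1, 2, NA, 4, 5), units = "PgC yr-1")
#' s
#' @export
annual_series <- function(years, values, units = "", label = "") {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(years)) {
    stop("duplicate years in annual series", call. = FALSE)
  }
  if (is.unsorted(years, strictly = TRUE)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  structure(
    list(year = years, value = values,
         units = as.character(units), label = as.character(label)),
    class = "annual_series"
  )
}

#' @export
print.annual_series <- function(x, ...) {
  n_na <- sum(is.na(x$value))
  cat(sprintf("<annual_series> %s [%s], %d-%d (%d years%s)\n",
              if (nzchar(x$label)) x$label else "unnamed",
              x$units, min(x$year), max(x$year), length(x$year),
              if (n_na > 0) sprintf(", %d missing", n_na) else ""))
  print(utils::head(data.frame(year = x$year, value = x$value), 6))
  if (length(x$year) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$year, value = x$value)
}

#' @export
length.annual_series <- function(x) length(x$year)

#' Extract values of an annual series for a set of years
#'
#' @param series An [annual_series()].
#' @param years Integer years to extract; years absent from the series return
#'   `NA`.
#' @return Numeric vector aligned with `years`.
#' @export
series_values <- function(series, years) {
  stopifnot(inherits(series, "annual_series"))
  series$value[match(as.integer(years), series$year)]
}

#' Read an annual series from a two-column CSV file
#'
#' The expected dialect is a header row `year,value` followed by one row per
#' year (the distribution style of the Global Carbon Project annual tables).
#' Year gaps are filled with explicit `NA` values so downstream code never
#' silently skips a year.
#'
#' @param path Path to the CSV file.
#' @param units,label Attached to the returned series.
#' @return An [annual_series()].
#' @export
read_annual_csv <- function(path, units = "", label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "value") %in% names(df))) {
    stop("annual CSV must have columns 'year' and 'value': ", path,
         call. = FALSE)
  }
  yr <- suppressWarnings(as.numeric(df$year))
  if (anyNA(yr) || any(yr != as.integer(yr))) {
    stop("non-integer year in ", path, call. = FALSE)
  }
  if (anyDuplicated(yr)) {
    stop("duplicated year in ", path, ": ",
         paste(unique(yr[duplicated(yr)]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$value)) {
    val <- suppressWarnings(as.numeric(df$value))
    bad <- !is.na(df$value) & df$value != "" & is.na(val)
    if (any(bad)) {
      stop("non-numeric value in ", path, " (year ",
           paste(yr[bad], collapse = ", "), ")", call. = FALSE)
    }
    df$value <- val
  }
  o <- order(yr)
  yr <- as.integer(yr[o])
  val <- df$value[o]
  full <- seq(min(yr), max(yr))
  annual_series(full, val[match(full, yr)], units = units, label = label)
}

#' Write an annual series to a two-column CSV file
#'
#' @param series An [annual_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annual_csv <- function(series, path) {
  stopifnot(inherits(series, "annual_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
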