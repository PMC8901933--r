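#' Gridded monthly climate field
#'
#' A lat x lon x month raster of one climate field (typically precipitation in
#' mm per month). The canonical internal orientation is ascending latitude
#' (south to north) and longitude in [-180, 180); constructors and readers
#' normalise to it so no downstream code has to guess. Months are contiguous
#' calendar months starting in January of `start_year`; missing data are `NA`
#' in `values`.
#'
#' @param lat Ascending vector of pixel-centre latitudes (degrees north).
#' @param lon Vector of pixel-centre longitudes (degrees east, [-180, 180)).
#' @param values Numeric array, `dim = c(length(lat), length(lon), n_months)`.
#' @param start_year First calendar year; month 1 is January of that year.
#' @param units Unit label for the field.
#' @return An object of class `monthly_grid` with elements `lat`, `lon`,
#'   `values`, `months` (data frame `year`, `month`) and `units`.
#' @export
monthly_grid <- function(lat, lon, values, start_year, units = "mm") {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("`values` must be a 3-d array [lat, lon, month]", call. = FALSE)
  }
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon)) {
    stop("array dimensions inconsistent with coordinates", call. = FALSE)
  }
  if (is.unsorted(lat, strictly = TRUE)) {
    o <- order(lat)
    lat <- lat[o]
    values <- values[o, , , drop = FALSE]
  }
  n_months <- dim(values)[3]
  start_year <- as.integer(start_year)
  months <- data.frame(
    year = start_year + (seq_len(n_months) - 1L) %/% 12L,
    month = (seq_len(n_months) - 1L) %% 12L + 1L
  )
  structure(
    list(lat = lat, lon = lon, values = values, months = months,
         units = as.character(units)),
    class = "monthly_grid"
  )
}

#' @export
print.monthly_grid <- function(x, ...) {
  cat(sprintf(
    "<monthly_grid> %d x %d pixels, %d months (%d-%02d to %d-%02d) [%s]\n",
    length(x$lat), length(x$lon), nrow(x$months),
    x$months$year[1], x$months$month[1],
    x$months$year[nrow(x$months)], x$months$month[nrow(x$months)], x$units))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f, %d masked cells\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              sum(is.na(x$values))))
  invisible(x)
}

#' Index of a calendar month along the grid's time axis
#'
#' @param grid A [monthly_grid()].
#' @param year,month Calendar year and month (1-12).
#' @return Integer index into the third array dimension, `NA` if outside.
#' @export
month_index <- function(grid, year, month) {
  match(paste(year, month), paste(grid$months$year, grid$months$month))
}

#' Write a monthly grid as a long-format CSV file
#'
#' One row per pixel-month with columns `lat,lon,year,month,value`; masked
#' cells are written as empty values. The format is deliberately plain text
#' so grids survive any transport and are diffable.
#'
#' @param grid A [monthly_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_grid <- function(grid, path) {
  stopifnot(inherits(grid, "monthly_grid"))
  nl <- length(grid$lat); no <- length(grid$lon); nm <- nrow(grid$months)
  df <- data.frame(
    lat = rep(grid$lat, times = no * nm),
    lon = rep(rep(grid$lon, each = nl), times = nm),
    year = rep(grid$months$year, each = nl * no),
    month = rep(grid$months$month, each = nl * no),
    value = as.vector(grid$values)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a monthly grid from a long-format CSV file
#'
#' Validates that the time axis is a contiguous run of calendar months and
#' normalises latitude to ascending (south-to-north) order. Missing cells
#' (empty values) come back as `NA`.
#'
#' @param path Path to a CSV written in the `lat,lon,year,month,value` layout
#'   (see [write_monthly_grid()]).
#' @param units Unit label to attach.
#' @return A [monthly_grid()].
#' @export
read_monthly_grid <- function(path, units = "mm") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "year", "month", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("grid CSV missing coordinate column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  mk <- df$year * 12L + (df$month - 1L)
  months <- sort(unique(mk))
  if (length(months) > 1 && !all(diff(months) == 1L)) {
    stop("time axis is not contiguous calendar months", call. = FALSE)
  }
  nl <- length(lat); no <- length(lon); nm <- length(months)
  values <- array(NA_real_, dim = c(nl, no, nm))
  idx <- cbind(match(df$lat, lat), match(df$lon, lon), match(mk, months))
  values[idx] <- df$value
  g <- monthly_grid(lat, lon, values, start_year = months[1] %/% 12L,
                    units = units)
  # reconstruct true first month (monthly_grid assumes January start)
  g$months <- data.frame(year = months %/% 12L, month = months %% 12L + 1L)
  g
}
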