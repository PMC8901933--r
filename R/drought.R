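#' Drought severity band configuration
#'
#' Percentile thresholds (percent) splitting local monthly precipitation
#' into severity bands. With the default thresholds 1, 10, 25, 50 the bands
#' are `very_extreme` [0,1), `extreme` [1,10), `mild` [10,25),
#' `natural_deficit` [25,50) and `none` [50,100]; membership is half-open
#' on the lower side.
#'
#' @param thresholds Strictly increasing percentiles in (0, 100].
#' @return A list of class `drought_bands` with `thresholds` and `labels`.
#' @export
drought_bands <- function(thresholds = c(1, 10, 25, 50)) {
  if (any(thresholds <= 0) || any(thresholds > 100) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing in (0, 100]",
         call. = FALSE)
  }
  default_labels <- c("very_extreme", "extreme", "mild", "natural_deficit")
  nb <- length(thresholds)
  labels <- c(if (nb <= length(default_labels)) default_labels[seq_len(nb)]
              else paste0("band", seq_len(nb)), "none")
  structure(list(thresholds = thresholds, labels = labels),
            class = "drought_bands")
}

#' Per-pixel empirical precipitation percentiles
#'
#' Converts each pixel's monthly precipitation to its empirical percentile
#' among that pixel's reference months, pooling all calendar months. The
#' percentile of a month with average rank r among n reference months is
#' `100 * (r - 0.5) / n` (ties share their average rank), so band
#' occupation over the reference period matches nominal band widths up to
#' the discreteness of n. Pixels where more than 30% of reference months
#' share a single value (e.g. desert-margin strings of zeros) are flagged
#' degenerate: their percentiles are undefined and they are excluded from
#' drought-area accounting.
#'
#' @param grid A [monthly_grid()] of monthly precipitation.
#' @param reference Optional `c(first, last)` month indexes of the reference
#'   period (default the full record). At least 120 reference months.
#' @param degenerate_tie_fraction Mode-share above which a pixel is flagged.
#' @return An object of class `percentile_field`: list with `pct` (array
#'   [lat, lon, month] of percentiles in [0, 100]), `degenerate` (logical
#'   matrix), and the grid coordinates.
#' @export
pixel_percentiles <- function(grid, reference = NULL,
                              degenerate_tie_fraction = 0.30) {
  stopifnot(inherits(grid, "monthly_grid"))
  nm <- nrow(grid$months)
  if (is.null(reference)) reference <- c(1L, nm)
  ref_idx <- seq(reference[1], reference[2])
  if (any(ref_idx < 1) || any(ref_idx > nm)) {
    stop("reference period outside grid months", call. = FALSE)
  }
  if (length(ref_idx) < 120) {
    stop("need at least 120 reference months per pixel", call. = FALSE)
  }
  nl <- length(grid$lat); no <- length(grid$lon)
  vmat <- matrix(grid$values, nrow = nl * no) # pixels x months
  nref <- length(ref_idx)
  full_ref <- identical(ref_idx, seq_len(nm))
  pct <- matrix(NA_real_, nl * no, nm)
  degenerate <- logical(nl * no)
  for (p in seq_len(nl * no)) {
    ref <- vmat[p, ref_idx]
    if (anyNA(ref)) { degenerate[p] <- TRUE; next }
    tie_share <- max(tabulate(match(ref, unique(ref)))) / nref
    if (tie_share > degenerate_tie_fraction) { degenerate[p] <- TRUE; next }
    if (full_ref) {
      r <- rank(ref, ties.method = "average")
      pct[p, ] <- 100 * (r - 0.5) / nref
    } else {
      sr <- sort(ref)
      v <- vmat[p, ]
      n_lt <- findInterval(v, sr, left.open = TRUE)  # reference months < v
      n_le <- findInterval(v, sr, left.open = FALSE) # reference months <= v
      avg_rank <- n_lt + (n_le - n_lt + 1) / 2
      pct[p, ] <- 100 * (avg_rank - 0.5) / nref
    }
  }
  structure(
    list(pct = array(pct, dim = c(nl, no, nm)),
         degenerate = matrix(degenerate, nl, no),
         lat = grid$lat, lon = grid$lon, months = grid$months,
         reference = reference),
    class = "percentile_field"
  )
}

#' Classify pixel-months into drought severity bands
#'
#' Total half-open band assignment by percentile: a pixel-month with
#' percentile p falls in band i when `thresholds[i-1] <= p < thresholds[i]`
#' (the last band `none` is closed at 100). Degenerate pixels stay
#' unclassified.
#'
#' @param pf A [pixel_percentiles()] result.
#' @param bands A [drought_bands()] configuration.
#' @return An object of class `drought_categories`: `band` (integer array
#'   [lat, lon, month] indexing `labels`), `labels`, `degenerate`,
#'   coordinates and months.
#' @export
classify_drought <- function(pf, bands = drought_bands()) {
  stopifnot(inherits(pf, "percentile_field"),
            inherits(bands, "drought_bands"))
  band <- findInterval(pf$pct, bands$thresholds) + 1L
  band <- array(band, dim = dim(pf$pct))
  band[is.na(pf$pct)] <- NA_integer_
  structure(
    list(band = band, labels = bands$labels, degenerate = pf$degenerate,
         lat = pf$lat, lon = pf$lon, months = pf$months),
    class = "drought_categories"
  )
}

# month indexes of a window (calendar years start..end) on a category field
window_month_idx <- function(months, start_year, end_year) {
  which(months$year >= start_year & months$year <= end_year)
}

band_codes <- function(cat, band_labels) {
  codes <- match(band_labels, cat$labels)
  if (anyNA(codes)) {
    stop("unknown band label(s): ",
         paste(band_labels[is.na(codes)], collapse = ", "), call. = FALSE)
  }
  codes
}

# In-band frequency per pixel over a set of months: fraction of those
# months whose band is in `codes`. Returns a pixels-long vector.
pixel_band_frequency <- function(cat, codes, midx) {
  nl <- length(cat$lat); no <- length(cat$lon)
  bmat <- matrix(cat$band, nrow = nl * no)[, midx, drop = FALSE]
  rowMeans(matrix(bmat %in% codes, nrow = nl * no))
}

#' Windowed frequency-weighted drought-affected area
#'
#' For each window, each non-degenerate vegetated pixel contributes its
#' cos-latitude area weighted by its drought frequency (the fraction of the
#' window's months in the requested band or band union); the region's
#' drought-affected area is the weighted sum expressed as a percentage of
#' the vegetated area. By default the denominator is the whole tropical
#' vegetated area, so continent/biome series read as "fraction of tropical
#' vegetated area"; set `denominator = "region"` for region-relative
#' fractions.
#'
#' @param cat A [classify_drought()] result.
#' @param mask A [region_mask()] aligned with the field.
#' @param windows Data frame from [enumerate_windows()] (any length/step).
#' @param band_labels Band or band union, e.g. `c("very_extreme","extreme")`.
#' @param region `"pantropic"`, a continent (`"T.America"`, `"T.Africa"`,
#'   `"T.Asia"`) or a biome (`"forest"`, `"semi_arid"`, `"other"`).
#' @param denominator `"pantropic"` (default) or `"region"`.
#' @return Data frame: `start_year`, `end_year`, `center_year`, `region`,
#'   `band`, `fraction` (percent of vegetated area), `sd_annual` (standard
#'   deviation of the window's annual fractions, the within-window
#'   variability).
#' @export
windowed_drought_area <- function(cat, mask, windows,
                                  band_labels = c("very_extreme", "extreme"),
                                  region = "pantropic",
                                  denominator = c("pantropic", "region")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(cat, "drought_categories"))
  codes <- band_codes(cat, band_labels)
  sel <- region_selector(mask, region) & !cat$degenerate
  if (!any(sel)) stop("empty region: ", region, call. = FALSE)
  den_sel <- if (denominator == "pantropic") {
    region_selector(mask, "pantropic") & !cat$degenerate
  } else sel
  w <- as.vector(mask$area)
  num_w <- w * as.vector(sel)
  den <- sum(w[as.vector(den_sel)])
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    midx <- window_month_idx(cat$months, windows$start_year[i],
                             windows$end_year[i])
    if (!length(midx)) stop("window outside classified months", call. = FALSE)
    freq <- pixel_band_frequency(cat, codes, midx)
    frac <- 100 * sum(freq * num_w) / den
    yrs <- unique(cat$months$year[midx])
    ann <- vapply(yrs, function(y) {
      yi <- midx[cat$months$year[midx] == y]
      100 * sum(pixel_band_frequency(cat, codes, yi) * num_w) / den
    }, numeric(1))
    data.frame(start_year = windows$start_year[i],
               end_year = windows$end_year[i],
               center_year = (windows$start_year[i] + windows$end_year[i]) / 2,
               region = region, band = paste(band_labels, collapse = "+"),
               fraction = frac,
               sd_annual = if (length(ann) > 1) stats::sd(ann) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Drought hotspot mask for one window
#'
#' A pixel is a hotspot when it spends strictly more than `time_fraction`
#' (default 10%) of the window's months in the requested band union.
#'
#' @inheritParams windowed_drought_area
#' @param window One row of [enumerate_windows()] output (or a list with
#'   `start_year`, `end_year`).
#' @param time_fraction Threshold fraction of window months.
#' @return Logical matrix [lat, lon]; degenerate pixels are `FALSE`.
#' @export
hotspot_mask <- function(cat, window,
                         band_labels = c("very_extreme", "extreme"),
                         time_fraction = 0.10) {
  codes <- band_codes(cat, band_labels)
  midx <- window_month_idx(cat$months, window$start_year, window$end_year)
  if (!length(midx)) stop("window outside classified months", call. = FALSE)
  freq <- pixel_band_frequency(cat, codes, midx)
  out <- matrix(freq > time_fraction, length(cat$lat), length(cat$lon))
  out[cat$degenerate] <- FALSE
  out
}

#' Regional and biome drought-area breakdown
#'
#' Evaluates [windowed_drought_area()] for the pantropic domain, each
#' continent and each biome, all expressed as fractions of the total
#' tropical vegetated area so that continent fractions sum to the pantropic
#' fraction.
#'
#' @inheritParams windowed_drought_area
#' @return Long data frame stacking the per-region series.
#' @export
regional_breakdown <- function(cat, mask, windows,
                               band_labels = c("very_extreme", "extreme")) {
  regions <- c("pantropic", "T.America", "T.Africa", "T.Asia",
               "forest", "semi_arid")
  out <- list()
  for (r in regions) {
    sel <- region_selector(mask, r)
    if (!any(sel)) {
      warning("region '", r, "' has no vegetated pixels; skipped")
      next
    }
    out[[r]] <- windowed_drought_area(cat, mask, windows, band_labels,
                                      region = r,
                                      denominator = "pantropic")
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
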