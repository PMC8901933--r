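#' Region, biome and vegetation mask aligned with a grid
#'
#' Static grid-aligned labels used for regional aggregation: a continent
#' label (`T.America`, `T.Africa`, `T.Asia`), a biome label (`forest`,
#' `semi_arid`, `other`), a logical vegetated flag and an optional
#' nonnegative net-ecosystem-exchange (NEE) magnitude weight used by the
#' regional partition. Pixel area weights are proportional to the cosine of
#' latitude, the standard equal-angle grid area factor.
#'
#' @param lat,lon Pixel-centre coordinates (ascending latitude).
#' @param continent,biome Character matrices `[lat, lon]` of labels; may be
#'   `NA` where not vegetated.
#' @param vegetated Logical matrix `[lat, lon]`.
#' @param nee_weight Optional nonnegative numeric matrix `[lat, lon]`.
#' @return An object of class `region_mask` with the above fields plus an
#'   `area` matrix of cos-latitude weights.
#' @export
region_mask <- function(lat, lon, continent, biome, vegetated,
                        nee_weight = NULL) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  dm <- c(length(lat), length(lon))
  for (m in list(continent, biome, vegetated)) {
    if (!all(dim(m) == dm)) {
      stop("mask matrices must be [lat, lon]", call. = FALSE)
    }
  }
  vegetated <- matrix(as.logical(vegetated), dm[1], dm[2])
  if (any(vegetated & (is.na(continent) | is.na(biome)))) {
    stop("continent/biome labels must be defined wherever vegetated",
         call. = FALSE)
  }
  if (!is.null(nee_weight)) {
    if (!all(dim(nee_weight) == dm) || any(nee_weight < 0, na.rm = TRUE)) {
      stop("nee_weight must be a nonnegative [lat, lon] matrix",
           call. = FALSE)
    }
  }
  area <- matrix(cos(lat * pi / 180), dm[1], dm[2])
  if (any(area <= 0)) stop("area weights must be positive", call. = FALSE)
  structure(
    list(lat = lat, lon = lon, continent = continent, biome = biome,
         vegetated = vegetated, nee_weight = nee_weight, area = area),
    class = "region_mask"
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d x %d pixels, %d vegetated (%.0f%%)\n",
              length(x$lat), length(x$lon), sum(x$vegetated),
              100 * mean(x$vegetated)))
  cat("  continents:", paste(names(table(x$continent[x$vegetated])),
                             collapse = ", "), "\n")
  cat("  biomes:    ", paste(names(table(x$biome[x$vegetated])),
                             collapse = ", "), "\n")
  invisible(x)
}

# Logical [lat, lon] selector for a named region. "pantropic" selects all
# vegetated pixels; continent and biome labels select their subsets.
region_selector <- function(mask, region) {
  sel <- switch(region,
    pantropic = matrix(TRUE, length(mask$lat), length(mask$lon)),
    T.America = ,
    T.Africa = ,
    T.Asia = !is.na(mask$continent) & mask$continent == region,
    forest = ,
    semi_arid = ,
    other = !is.na(mask$biome) & mask$biome == region,
    stop("unknown region: ", region, call. = FALSE)
  )
  sel & mask$vegetated
}

#' Write / read a region mask as CSV
#'
#' Long-format CSV with one row per pixel:
#' `lat,lon,continent,biome,vegetated,nee_weight`.
#'
#' @param mask A [region_mask()].
#' @param path File path.
#' @return `path` (write) or a [region_mask()] (read).
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  nl <- length(mask$lat); no <- length(mask$lon)
  df <- data.frame(
    lat = rep(mask$lat, times = no),
    lon = rep(mask$lon, each = nl),
    continent = as.vector(mask$continent),
    biome = as.vector(mask$biome),
    vegetated = as.vector(mask$vegetated),
    nee_weight = if (is.null(mask$nee_weight)) NA_real_
                 else as.vector(mask$nee_weight)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  nl <- length(lat); no <- length(lon)
  idx <- cbind(match(df$lat, lat), match(df$lon, lon))
  take <- function(col, mode) {
    m <- matrix(vector(mode, 1L), nl, no)
    m[idx] <- col
    m
  }
  continent <- take(ifelse(df$continent == "", NA, df$continent), "character")
  biome <- take(ifelse(df$biome == "", NA, df$biome), "character")
  vegetated <- take(df$vegetated, "logical")
  nee <- if (all(is.na(df$nee_weight))) NULL else take(df$nee_weight, "numeric")
  region_mask(lat, lon, continent, biome, vegetated, nee)
}
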