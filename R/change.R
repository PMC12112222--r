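#' Binarize a suitability surface at a threshold
#'
#' Suitable (1) iff HSI strictly exceeds the threshold, else 0; equality is
#' non-suitable, preserving "suitable means exceeding the threshold".
#'
#' @param suit an `sdm_raster` of suitability in \[0, 1\].
#' @param mtsps the threshold.
#' @return binary `sdm_raster` (0/1).
#' @export
binarize_suitability <- function(suit, mtsps) {
  v <- suit$values
  vv <- v[!is.na(v)]
  if (any(vv < 0 | vv > 1)) stop("suitability values must lie in [0, 1]")
  b <- ifelse(is.na(v), NA_real_, as.numeric(v > mtsps))
  h <- suit$header
  new_raster(b, h$xll, h$yll, h$cellsize, h$nodata)
}

#' Range-change map between two binary rasters
#'
#' Cell coding: 0 absent in both periods, -1 expansion (absent now, present
#' later), 1 stable presence, 2 contraction (present now, absent later).
#'
#' @param current_bin,future_bin aligned binary `sdm_raster`s.
#' @return `sdm_raster` of codes \{0, -1, 1, 2\}.
#' @export
change_map <- function(current_bin, future_bin) {
  if (!same_header(current_bin, future_bin))
    stop("current and future rasters are not aligned (header mismatch)")
  a <- current_bin$values; b <- future_bin$values
  code <- matrix(NA_real_, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  code[ok & a == 0 & b == 0] <- 0
  code[ok & a == 0 & b == 1] <- -1
  code[ok & a == 1 & b == 1] <- 1
  code[ok & a == 1 & b == 0] <- 2
  h <- current_bin$header
  new_raster(code, h$xll, h$yll, h$cellsize, h$nodata)
}

#' Range-change percentages from areas
#'
#' `range_change = (future - current) / current * 100`,
#' `pct_loss = loss / current * 100`, `pct_gain = gain / current * 100`.
#'
#' @param area_current,area_future,gain,loss areas in any common unit;
#'   `area_current` must be positive.
#' @return named list of the three percentages.
#' @export
change_percentages <- function(area_current, area_future, gain, loss) {
  if (area_current <= 0) stop("percentages undefined: current area is zero")
  list(range_change_pct = (area_future - area_current) / area_current * 100,
       pct_loss = loss / area_current * 100,
       pct_gain = gain / area_current * 100)
}

#' Area accounting of a range-change map
#'
#' Latitude-corrected areas of the gain (-1), stable (1) and loss (2)
#' codes; the identities `area_current = stable + loss` and
#' `area_future = stable + gain = area_current + gain - loss` hold exactly
#' by construction.
#'
#' @param cmap a [change_map()] raster.
#' @return data.frame with `area_current`, `area_future`, `gain`, `stable`,
#'   `loss` (km^2) and `range_change_pct`, `pct_loss`, `pct_gain`.
#' @export
change_stats <- function(cmap) {
  cells <- which(!is.na(as.vector(cmap$values)))
  lat <- cell_lonlat(cmap, cells)$lat
  a <- cell_area_km2(lat, cmap$header$cellsize)
  code <- cmap$values[cells]
  gain <- sum(a[code == -1]); stable <- sum(a[code == 1]); loss <- sum(a[code == 2])
  cur <- stable + loss; fut <- stable + gain
  pct <- change_percentages(cur, fut, gain, loss)
  data.frame(area_current = cur, area_future = fut, gain = gain,
             stable = stable, loss = loss,
             range_change_pct = pct$range_change_pct,
             pct_loss = pct$pct_loss, pct_gain = pct$pct_gain)
}

#' Centroid of the suitable range
#'
#' Area-weighted mean of suitable-cell center coordinates (weights =
#' spherical cell areas).
#'
#' @param bin binary `sdm_raster` with at least one suitable cell.
#' @return named vector `c(lon, lat)`.
#' @export
suitable_centroid <- function(bin) {
  cells <- which(as.vector(bin$values) == 1)
  if (length(cells) == 0) stop("no suitable cells: centroid undefined")
  ll <- cell_lonlat(bin, cells)
  w <- cell_area_km2(ll$lat, bin$header$cellsize)
  c(lon = sum(w * ll$lon) / sum(w), lat = sum(w * ll$lat) / sum(w))
}

#' Compass sector of a bearing
#'
#' Eight 45-degree sectors centered on the cardinal and intercardinal
#' directions.
#'
#' @param bearing degrees clockwise from north.
#' @return one of `N`, `NE`, `E`, `SE`, `S`, `SW`, `W`, `NW`.
#' @export
compass_sector <- function(bearing) {
  sectors <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  sectors[(round(bearing / 45) %% 8) + 1]
}

#' Centroid shift kinematics
#'
#' Great-circle distance, initial bearing, compass sector, and speed
#' (distance / years) between two range centroids.
#'
#' @param c_from,c_to centroids as `c(lon, lat)`.
#' @param years elapsed years between the periods (> 0); consecutive
#'   climate-scenario decades ("2050s" to "2070s") span 20 years.
#' @return list with `from`, `to`, `distance_km`, `bearing_deg`,
#'   `direction`, `years`, `speed_km_per_yr`.
#' @export
centroid_shift <- function(c_from, c_to, years = 20) {
  stopifnot(years > 0)
  d <- haversine_km(c_from[["lon"]], c_from[["lat"]], c_to[["lon"]], c_to[["lat"]])
  b <- bearing_deg(c_from[["lon"]], c_from[["lat"]], c_to[["lon"]], c_to[["lat"]])
  list(from = c_from, to = c_to, distance_km = d, bearing_deg = b,
       direction = compass_sector(b), years = years, speed_km_per_yr = d / years)
}
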