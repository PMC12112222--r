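#' Load and clean presence records
#'
#' Reads a `name,longitude,latitude` CSV (or takes an equivalent
#' data.frame), drops rows with unparseable or out-of-range coordinates,
#' collapses exact duplicate coordinates to one record, and — when a mask
#' raster is supplied — drops records that fall on masked cells or outside
#' the raster extent. A cleaning log with per-step counts is attached as
#' attribute `"cleaning"`.
#'
#' @param x path to a CSV file with columns `name`, `longitude`, `latitude`,
#'   or a data.frame with those columns.
#' @param mask optional `sdm_raster`; records on its masked cells are
#'   dropped.
#' @return data.frame with columns `name`, `longitude`, `latitude` and
#'   attribute `cleaning` (named counts plus log lines).
#' @export
load_occurrences <- function(x, mask = NULL) {
  df <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else as.data.frame(x)
  need <- c("name", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence table must have columns: ", paste(need, collapse = ", "))
  n_input <- nrow(df)
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  ok <- is.finite(lon) & is.finite(lat) & lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_bad <- sum(!ok)
  df <- data.frame(name = as.character(df$name)[ok], longitude = lon[ok],
                   latitude = lat[ok], stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("longitude", "latitude")])
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  n_masked <- 0L
  if (!is.null(mask)) {
    cells <- lonlat_cell(mask, df$longitude, df$latitude)
    on_mask <- !is.na(cells) & !is.na(mask$values[cells])
    n_masked <- sum(!on_mask)
    df <- df[on_mask, , drop = FALSE]
  }
  rownames(df) <- NULL
  log_lines <- c(
    sprintf("input records: %d", n_input),
    sprintf("dropped (unparseable or out-of-range coordinates): %d", n_bad),
    sprintf("collapsed exact duplicate coordinates: %d", n_dup),
    if (!is.null(mask)) sprintf("dropped (masked or off-grid cells): %d", n_masked),
    sprintf("retained: %d", nrow(df)))
  attr(df, "cleaning") <- list(n_input = n_input, n_bad_coord = n_bad, n_duplicate = n_dup,
                               n_masked = n_masked, n_kept = nrow(df), log = log_lines)
  df
}

#' Spatially thin presence records
#'
#' Greedy thinning: records are visited in a seed-shuffled order and kept
#' iff their great-circle distance to every already-kept record is at least
#' `min_km`. The result has pairwise minimum distance >= `min_km` and is a
#' maximal independent set for the visiting order.
#'
#' The default 2.5 km matches a thinning buffer commonly paired with
#' 2.5 arc-min climate grids; one-point-per-cell behaviour is obtained by
#' setting `min_km` to the cell ground size instead.
#'
#' @param occ occurrence data.frame (`longitude`, `latitude` columns).
#' @param min_km minimum pairwise distance to enforce, km.
#' @param seed integer seed controlling the visiting order.
#' @return thinned occurrence data.frame.
#' @export
thin_occurrences <- function(occ, min_km = 2.5, seed = NULL) {
  stopifnot(min_km > 0)
  n <- nrow(occ)
  if (n == 0) return(occ)
  if (!is.null(seed)) set.seed(seed)
  ord <- sample.int(n)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0 ||
        all(haversine_km(occ$longitude[i], occ$latitude[i],
                         occ$longitude[kept], occ$latitude[kept]) >= min_km)) {
      kept <- c(kept, i)
    }
  }
  out <- occ[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}
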