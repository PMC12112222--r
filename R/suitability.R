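#' Maximum test sensitivity plus specificity threshold
#'
#' Scans the candidate set of observed prediction values and returns the
#' threshold maximizing sensitivity (fraction of test presences at or above
#' the threshold) plus specificity (fraction of background strictly below
#' it); ties return the smallest such threshold. Background points act as
#' pseudo-absences, the standard presence-only convention.
#'
#' @param pred_presence predictions at (test) presences.
#' @param pred_background predictions at background points.
#' @return the MTSPS threshold.
#' @export
mtsps_threshold <- function(pred_presence, pred_background) {
  stopifnot(length(pred_presence) > 0, length(pred_background) > 0)
  cand <- sort(unique(c(pred_presence, pred_background)))
  score <- vapply(cand, function(t)
    mean(pred_presence >= t) + mean(pred_background < t), numeric(1))
  cand[which(score == max(score))[1]]
}

#' Suitability grade scheme from an MTSPS threshold
#'
#' Grade bounds are multiples of the threshold — `(t, 2t, 3t)` capped at 1 —
#' generalizing the conventional 0.22 / 0.44 / 0.66 grading to any
#' threshold.
#'
#' @param mtsps threshold in (0, 1).
#' @return object of class `grade_scheme` with `mtsps` and `bounds`
#'   `(t1, t2, t3)`.
#' @export
grade_scheme <- function(mtsps = 0.22) {
  stopifnot(mtsps > 0, mtsps < 1)
  b <- pmin(c(t1 = mtsps, t2 = 2 * mtsps, t3 = 3 * mtsps), 1)
  if (!(b[1] < b[2] && b[2] < b[3]))
    stop("grade bounds collapse (mtsps too large for three distinct grades)")
  structure(list(mtsps = mtsps, bounds = b), class = "grade_scheme")
}

#' Classify a suitability surface into four grades
#'
#' Half-open intervals with boundary values belonging to the higher class:
#' 0 = non-suitable (`p < t1`), 1 = low (`t1 <= p < t2`), 2 = medium
#' (`t2 <= p < t3`), 3 = high (`p >= t3`).
#'
#' @param suit an `sdm_raster` of suitability in \[0, 1\].
#' @param scheme a [grade_scheme()].
#' @return `sdm_raster` of grade codes 0-3.
#' @export
classify_suitability <- function(suit, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  v <- suit$values
  vv <- v[!is.na(v)]
  if (any(vv < 0 | vv > 1)) stop("suitability values must lie in [0, 1]")
  g <- matrix(NA_real_, nrow(v), ncol(v))
  g[!is.na(v)] <- findInterval(vv, scheme$bounds)
  h <- suit$header
  new_raster(g, h$xll, h$yll, h$cellsize, h$nodata)
}

#' Latitude-corrected area per suitability grade
#'
#' Sums [cell_area_km2()] at each cell's center latitude, per grade code.
#'
#' @param grades an `sdm_raster` of codes 0-3 from [classify_suitability()].
#' @return data.frame with one row per grade (`none`, `low`, `medium`,
#'   `high`) plus a `total_suitable` row (low + medium + high), areas in
#'   km^2.
#' @export
area_report <- function(grades) {
  h <- grades$header
  cells <- which(!is.na(as.vector(grades$values)))
  lat <- cell_lonlat(grades, cells)$lat
  a <- cell_area_km2(lat, h$cellsize)
  code <- grades$values[cells]
  per <- vapply(0:3, function(g) sum(a[code == g]), numeric(1))
  data.frame(grade = c("none", "low", "medium", "high", "total_suitable"),
             area_km2 = c(per, sum(per[2:4])), stringsAsFactors = FALSE)
}

#' Distribution proportions across suitability grades
#'
#' `100 * x / sum(x)` for per-grade record counts or areas.
#'
#' @param x named nonnegative vector of counts or areas with positive
#'   total.
#' @return percentage vector summing to 100.
#' @export
distribution_proportion <- function(x) {
  total <- sum(x)
  if (!is.finite(total) || total <= 0) stop("total count/area must be positive")
  100 * x / total
}
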