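#' Georeferenced single-band raster grids
#'
#' `new_raster()` wraps a numeric matrix as a georeferenced grid in
#' geographic (WGS84) coordinates. Row 1 of the matrix is the northernmost
#' row; the header is corner-registered (`xll`, `yll` are the coordinates of
#' the outer corner of the south-west cell). Cells equal to the nodata
#' sentinel (or `NA`) are masked and excluded from all statistics.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` marks nodata.
#' @param xll,yll west / south edge of the grid, decimal degrees.
#' @param cellsize cell edge length in decimal degrees (> 0).
#' @param nodata sentinel written for masked cells on output.
#' @return an object of class `sdm_raster` with elements `header`
#'   (`ncols`, `nrows`, `xll`, `yll`, `cellsize`, `nodata`) and `values`.
#' @export
new_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  header <- list(ncols = ncol(values), nrows = nrow(values),
                 xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize), nodata = as.numeric(nodata))
  validate_header(header)
  structure(list(header = header, values = values), class = "sdm_raster")
}

validate_header <- function(h) {
  if (h$ncols < 1 || h$nrows < 1) stop("raster must have at least one row and column")
  if (!is.finite(h$cellsize) || h$cellsize <= 0) stop("cellsize must be > 0")
  xmax <- h$xll + h$ncols * h$cellsize
  ymax <- h$yll + h$nrows * h$cellsize
  if (h$xll < -180 - 1e-9 || xmax > 180 + 1e-9 || h$yll < -90 - 1e-9 || ymax > 90 + 1e-9)
    stop("raster extent must lie within [-180,180] x [-90,90]")
  invisible(h)
}

#' @export
print.sdm_raster <- function(x, ...) {
  h <- x$header
  cat(sprintf("<sdm_raster> %d rows x %d cols, cellsize %g deg\n", h$nrows, h$ncols, h$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              h$xll, h$xll + h$ncols * h$cellsize, h$yll, h$yll + h$nrows * h$cellsize))
  v <- raster_mask(x)
  cat(sprintf("  valid cells: %d / %d\n", sum(v), length(v)))
  invisible(x)
}

#' Validity mask of a raster
#'
#' @param r an `sdm_raster`.
#' @return logical matrix, `TRUE` where the cell carries data.
#' @export
raster_mask <- function(r) !is.na(r$values)

same_header <- function(a, b, tol = 1e-9) {
  ha <- a$header; hb <- b$header
  ha$ncols == hb$ncols && ha$nrows == hb$nrows &&
    abs(ha$xll - hb$xll) < tol && abs(ha$yll - hb$yll) < tol &&
    abs(ha$cellsize - hb$cellsize) < tol
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, `NODATA_value`) followed by
#' `nrows * ncols` whitespace-separated values, first data row =
#' northernmost. Center-registered files are converted to the corner
#' convention (`xll = xllcenter - cellsize/2`). Cells equal to the nodata
#' sentinel (relative tolerance 1e-6) are masked.
#'
#' @param path file path.
#' @return an [new_raster()] object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L, warn = FALSE)
  if (length(lines) < 6L) stop("ASCII grid header truncated: expected 6 header lines in ", path)
  kv <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop(sprintf("malformed ASCII grid header at line %d: '%s'", i, lines[[i]]))
    list(key = tolower(parts[1]), value = as.numeric(parts[2]))
  })
  keys <- vapply(kv, `[[`, "", "key")
  vals <- vapply(kv, `[[`, 0, "value")
  get_key <- function(alts, what) {
    i <- which(keys %in% alts)
    if (length(i) != 1L) stop("ASCII grid header missing or duplicated field: ", what)
    vals[[i]]
  }
  ncols <- as.integer(get_key("ncols", "ncols"))
  nrows <- as.integer(get_key("nrows", "nrows"))
  cellsize <- get_key("cellsize", "cellsize")
  nodata <- get_key("nodata_value", "NODATA_value")
  xll <- get_key(c("xllcorner", "xllcenter"), "xllcorner")
  yll <- get_key(c("yllcorner", "yllcenter"), "yllcorner")
  if ("xllcenter" %in% keys) xll <- xll - cellsize / 2
  if ("yllcenter" %in% keys) yll <- yll - cellsize / 2

  vals_num <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals_num) != nrows * ncols)
    stop(sprintf("ASCII grid dimension mismatch: header promises %d x %d = %d values, found %d",
                 nrows, ncols, nrows * ncols, length(vals_num)))
  m <- matrix(vals_num, nrow = nrows, ncol = ncols, byrow = TRUE)
  tol <- 1e-6 * max(1, abs(nodata))
  m[abs(m - nodata) <= tol] <- NA_real_
  new_raster(m, xll, yll, cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Writes the corner-convention 6-line header and the data rows north to
#' south; masked cells are written as the nodata sentinel. Values are
#' printed with enough significant digits that `read_ascii_grid()` recovers
#' them to printed precision.
#'
#' @param r an `sdm_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  h <- r$header
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", h$ncols),
    sprintf("nrows %d", h$nrows),
    sprintf("xllcorner %.10g", h$xll),
    sprintf("yllcorner %.10g", h$yll),
    sprintf("cellsize %.10g", h$cellsize),
    sprintf("NODATA_value %.10g", h$nodata)), con)
  v <- r$values
  v[is.na(v)] <- h$nodata
  rows <- apply(v, 1, function(row) paste(sprintf("%.10g", row), collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Cell-center coordinates of raster cells
#'
#' Cells are addressed by their linear index into the values matrix
#' (column-major, as R stores it).
#'
#' @param r an `sdm_raster` (or a bare header list).
#' @param cells integer vector of linear cell indices.
#' @return data.frame with columns `lon`, `lat`.
#' @export
cell_lonlat <- function(r, cells) {
  h <- if (inherits(r, "sdm_raster")) r$header else r
  i <- (cells - 1L) %% h$nrows + 1L   # row, 1 = north
  j <- (cells - 1L) %/% h$nrows + 1L  # col
  data.frame(lon = h$xll + (j - 0.5) * h$cellsize,
             lat = h$yll + (h$nrows - i + 0.5) * h$cellsize)
}

#' Locate coordinates in a raster
#'
#' @param r an `sdm_raster`.
#' @param lon,lat coordinate vectors, decimal degrees.
#' @return integer linear cell indices; `NA` for points outside the extent.
#' @export
lonlat_cell <- function(r, lon, lat) {
  h <- if (inherits(r, "sdm_raster")) r$header else r
  j <- floor((lon - h$xll) / h$cellsize) + 1
  i <- h$nrows - floor((lat - h$yll) / h$cellsize)
  bad <- j < 1 | j > h$ncols | i < 1 | i > h$nrows | !is.finite(j) | !is.finite(i)
  idx <- as.integer(i + (j - 1) * h$nrows)
  idx[bad] <- NA_integer_
  idx
}

#' Geodesic area of a grid cell
#'
#' Spherical-Earth cell area at a given center latitude:
#' `(cellsize * K)^2 * cos(lat)` with `K = 111.19493` km per degree
#' (mean Earth radius 6371.0088 km).
#'
#' @param lat_center cell-center latitude, degrees (vectorized).
#' @param cellsize cell edge, degrees.
#' @return area in km^2.
#' @export
cell_area_km2 <- function(lat_center, cellsize) {
  stopifnot(all(abs(lat_center) <= 90))
  (cellsize * KM_PER_DEGREE)^2 * cos(lat_center * pi / 180)
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in WGS84 decimal degrees
#'   (vectorized).
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Azimuth at the start point of the great circle towards the end point,
#' degrees clockwise from north in \[0, 360).
#'
#' @inheritParams haversine_km
#' @return bearing in degrees.
#' @export
bearing_deg <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlon <- (lon2 - lon1) * to_rad
  y <- sin(dlon) * cos(lat2 * to_rad)
  x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
    sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
  (atan2(y, x) / to_rad) %% 360
}

#' Bundle aligned rasters into a named stack
#'
#' All layers must share one header; the joint mask is the intersection of
#' the layer masks.
#'
#' @param layers named list of `sdm_raster` objects.
#' @return an object of class `sdm_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("stack layers must be named")
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "sdm_raster")) stop("layer '", nm, "' is not an sdm_raster")
    if (!same_header(layers[[1]], layers[[nm]]))
      stop("layer '", nm, "' header differs from layer '", names(layers)[1], "'")
  }
  structure(list(header = layers[[1]]$header, layers = layers), class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  cat(sprintf("  %d rows x %d cols, cellsize %g deg; %d jointly valid cells\n",
              x$header$nrows, x$header$ncols, x$header$cellsize, length(valid_cells(x))))
  invisible(x)
}

#' Jointly valid cells of a stack
#'
#' @param stack an `sdm_stack`.
#' @return integer linear indices of cells valid in every layer.
#' @export
valid_cells <- function(stack) {
  ok <- Reduce(`&`, lapply(stack$layers, raster_mask))
  which(as.vector(ok))
}

#' Extract layer values at cells
#'
#' @param stack an `sdm_stack`.
#' @param cells linear cell indices.
#' @return numeric matrix, one named column per layer.
#' @export
stack_values <- function(stack, cells) {
  out <- vapply(stack$layers, function(l) l$values[cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  out
}

#' Sample background cells
#'
#' Draws cells uniformly without replacement from the jointly valid mask.
#' Presence cells are excluded by default (documented switch).
#'
#' @param stack an `sdm_stack`.
#' @param n number of background cells (capped at the number available).
#' @param seed integer seed for reproducibility.
#' @param exclude cell indices to exclude (e.g. presence cells); `NULL` for
#'   none.
#' @return integer vector of cell indices.
#' @export
sample_background <- function(stack, n = 10000, seed = NULL, exclude = NULL) {
  pool <- valid_cells(stack)
  if (!is.null(exclude)) pool <- setdiff(pool, exclude)
  if (length(pool) == 0) stop("no valid cells available for background sampling")
  if (!is.null(seed)) set.seed(seed)
  if (n >= length(pool)) return(pool)
  sort(sample(pool, n, replace = FALSE))
}
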