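test_that("ASCII grid write/read roundtrips exactly", {
  r <- demo_raster()
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  r2 <- read_ascii_grid(f)
  expect_equal(r2$header, r$header)
  expect_equal(r2$values, r$values)

  # arbitrary values with a masked cell
  set.seed(1)
  v <- matrix(rnorm(30), 5, 6)
  v[2, 3] <- NA
  r3 <- new_raster(v, -10, -5, 0.25)
  write_ascii_grid(r3, f)
  r4 <- read_ascii_grid(f)
  expect_equal(r4$values, r3$values, tolerance = 1e-9)
  expect_equal(sum(is.na(r4$values)), 1)

  # all-masked raster stays readable
  r5 <- new_raster(matrix(NA_real_, 2, 2), 0, 0, 1)
  write_ascii_grid(r5, f)
  expect_true(all(is.na(read_ascii_grid(f)$values)))

  # 1x1 raster prints its single token faithfully
  write_ascii_grid(new_raster(matrix(0.22), 0, 0, 1), f)
  expect_identical(readLines(f)[7], "0.22")
})

test_that("nodata cells are masked and center registration converts to corner", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcenter 10.0", "yllcorner 0",
               "cellsize 0.5", "NODATA_value -9999",
               "1 -9999", "3 4"), f)
  r <- read_ascii_grid(f)
  expect_equal(r$header$xll, 9.75)
  expect_equal(sum(is.na(r$values)), 1)
  expect_true(is.na(r$values[1, 2]))
})

test_that("malformed headers and dimension mismatches are reported", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows banana", "xllcorner 0", "yllcorner 0",
               "cellsize 0.5", "NODATA_value -9999", "1 2", "3 4"), f)
  expect_error(read_ascii_grid(f), "line 2")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 0.5", "NODATA_value -9999", "1 2 3"), f)
  expect_error(read_ascii_grid(f), "dimension mismatch")
})

test_that("cell areas follow the spherical cosine rule", {
  cs <- 2.5 / 60
  expect_equal(cell_area_km2(0, cs), 21.47, tolerance = 0.01 / 21.47)
  expect_equal(cell_area_km2(60, cs), cell_area_km2(0, cs) / 2)
  expect_equal(cell_area_km2(90, cs), 0)
  # 1x1 degree block centered on the equator sums to ~111.195^2 km^2
  lats <- seq(-0.5 + 0.05, 0.5 - 0.05, by = 0.1)
  block <- sum(outer(lats, 1:10, function(la, jj) cell_area_km2(la, 0.1)))
  expect_equal(block, 111.19493^2, tolerance = 0.005)
})

test_that("haversine distances are metric and match the latitude scale", {
  expect_equal(haversine_km(100, 25, 100, 25), 0)
  expect_equal(haversine_km(100, 25, 100, 26), 111.19, tolerance = 0.01 / 111.19)
  set.seed(42)
  pts <- matrix(c(runif(30, -180, 180), runif(30, -85, 85)), ncol = 2)
  for (i in 1:10) {
    p1 <- pts[i, ]; p2 <- pts[i + 10, ]; p3 <- pts[i + 20, ]
    expect_equal(haversine_km(p1[1], p1[2], p2[1], p2[2]),
                 haversine_km(p2[1], p2[2], p1[1], p1[2]))
    expect_lte(haversine_km(p1[1], p1[2], p3[1], p3[2]),
               haversine_km(p1[1], p1[2], p2[1], p2[2]) +
                 haversine_km(p2[1], p2[2], p3[1], p3[2]) + 1e-9)
  }
  # cross-check against an independent geodesy library
  d_pkg <- haversine_km(pts[1:10, 1], pts[1:10, 2], pts[11:20, 1], pts[11:20, 2])
  d_geo <- geosphere::distHaversine(pts[1:10, ], pts[11:20, ], r = 6371008.8) / 1000
  expect_equal(d_pkg, d_geo, tolerance = 1e-6)
})

test_that("cell indexing is its own inverse on cell centers", {
  r <- demo_raster()
  cells <- 1:9
  ll <- cell_lonlat(r, cells)
  expect_equal(lonlat_cell(r, ll$lon, ll$lat), cells)
  expect_true(is.na(lonlat_cell(r, 99, 25.1)))
})

test_that("stacks require aligned named layers and intersect masks", {
  a <- demo_raster()
  b <- demo_raster(matrix(c(1:8, NA), 3, 3))
  s <- raster_stack(list(x = a, y = b))
  expect_equal(length(valid_cells(s)), 8)
  shifted <- demo_raster(xll = 101)
  expect_error(raster_stack(list(x = a, y = shifted)), "header")
  expect_error(raster_stack(list(a, b)), "named")
})
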