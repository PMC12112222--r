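test_that("binarization uses the strict exceedance rule", {
  r <- new_raster(matrix(c(0.23, 0.22, 0.0, NA), 2, 2), 0, 0, 0.5)
  b <- binarize_suitability(r, 0.22)
  expect_equal(b$values[1, 1], 1)   # 0.23 > 0.22
  expect_equal(b$values[2, 1], 0)   # equality -> non-suitable
  expect_equal(b$values[1, 2], 0)
  expect_true(is.na(b$values[2, 2]))
  zero <- binarize_suitability(new_raster(matrix(0, 3, 3), 0, 0, 1), 0.22)
  expect_true(all(zero$values == 0))
})

test_that("change maps encode expansion/stability/contraction", {
  cur <- new_raster(matrix(c(1, 1, 0, 0), 2, 2), 0, 0, 0.5)
  fut <- new_raster(matrix(c(1, 0, 1, 0), 2, 2), 0, 0, 0.5)
  cm <- change_map(cur, fut)
  expect_equal(cm$values[1, 1], 1)    # stable
  expect_equal(cm$values[2, 1], 2)    # contraction
  expect_equal(cm$values[1, 2], -1)   # expansion
  expect_equal(cm$values[2, 2], 0)    # absent twice

  same <- change_map(cur, cur)
  expect_true(all(same$values %in% c(0, 1)))
  comp <- change_map(cur, new_raster(1 - cur$values, 0, 0, 0.5))
  expect_true(all(comp$values %in% c(-1, 2)))

  misaligned <- new_raster(matrix(0, 2, 2), 1, 0, 0.5)
  expect_error(change_map(cur, misaligned), "aligned")
})

test_that("change statistics satisfy the area budget identity exactly", {
  set.seed(17)
  cur <- new_raster(matrix(rbinom(400, 1, 0.4), 20, 20), 100, 20, 0.25)
  fut <- new_raster(matrix(rbinom(400, 1, 0.45), 20, 20), 100, 20, 0.25)
  st <- change_stats(change_map(cur, fut))
  expect_equal(st$area_future, st$area_current + st$gain - st$loss)
  expect_equal(st$stable, st$area_current - st$loss)
  expect_equal(st$range_change_pct,
               (st$area_future - st$area_current) / st$area_current * 100)
  expect_equal(st$pct_loss, st$loss / st$area_current * 100)
  expect_equal(st$pct_gain, st$gain / st$area_current * 100)
  # equal gain and loss cancel
  pc <- change_percentages(100, 100, 12, 12)
  expect_equal(pc$range_change_pct, 0)
  expect_error(change_percentages(0, 1, 0, 0), "zero")
})

test_that("composed change maps reproduce direct occupancy (set identity)", {
  set.seed(18)
  a <- new_raster(matrix(rbinom(100, 1, 0.5), 10, 10), 0, 0, 0.5)
  b <- new_raster(matrix(rbinom(100, 1, 0.5), 10, 10), 0, 0, 0.5)
  cc <- new_raster(matrix(rbinom(100, 1, 0.5), 10, 10), 0, 0, 0.5)
  occupied_after <- function(cm) cm$values %in% c(-1, 1)
  via_b <- occupied_after(change_map(b, cc))
  direct <- occupied_after(change_map(a, cc))
  expect_equal(via_b, direct)  # occupancy at C is independent of the path
})

test_that("range centroids are area-weighted and match brute force", {
  # single suitable cell -> its center
  one <- new_raster(matrix(c(1, 0, 0, 0), 2, 2), 100, 25, 0.5)
  expect_equal(suitable_centroid(one), c(lon = 100.25, lat = 25.75))

  # two equal-latitude cells symmetric about lon 100
  two <- new_raster(matrix(c(1, 1), 1, 2), 99, 25, 1)
  expect_equal(suitable_centroid(two)[["lon"]], 100)

  # latitude band 0..10 degrees: cos-weighting pulls equatorward
  band <- new_raster(matrix(1, 10, 1), 100, 0, 1)
  ct <- suitable_centroid(band)
  expect_lt(ct[["lat"]], 5)
  lat_centers <- 0:9 + 0.5
  expect_equal(ct[["lat"]],
               sum(lat_centers * cos(lat_centers * pi / 180)) /
                 sum(cos(lat_centers * pi / 180)))

  # brute-force oracle on a random map
  set.seed(19)
  v <- matrix(rbinom(200, 1, 0.3), 10, 20)
  r <- new_raster(v, 100, 20, 0.25)
  ct2 <- suitable_centroid(r)
  idx <- which(v == 1)
  ll <- cell_lonlat(r, idx)
  w <- cos(ll$lat * pi / 180)
  expect_equal(ct2[["lon"]], sum(w * ll$lon) / sum(w), tolerance = 1e-12)
  expect_equal(ct2[["lat"]], sum(w * ll$lat) / sum(w), tolerance = 1e-12)

  expect_error(suitable_centroid(new_raster(matrix(0, 2, 2), 0, 0, 1)), "centroid")
})

test_that("centroid shift kinematics: distance, bearing, sector, speed", {
  from <- c(lon = 100, lat = 30)
  north <- c(lon = 100, lat = 31)
  sh <- centroid_shift(from, north, years = 20)
  expect_equal(sh$bearing_deg, 0)
  expect_equal(sh$direction, "N")
  expect_equal(sh$speed_km_per_yr * sh$years, sh$distance_km, tolerance = 1e-9)

  same <- centroid_shift(from, from, years = 20)
  expect_equal(same$distance_km, 0)
  expect_equal(same$speed_km_per_yr, 0)

  # cardinal azimuths from closed-form cases
  expect_equal(bearing_deg(0, 0, 0.5, 0), 90)    # due east along the equator
  expect_equal(bearing_deg(0, 0, 0, -1), 180)
  expect_equal(bearing_deg(0, 0, -0.5, 0), 270)
  sh2 <- centroid_shift(from, c(lon = 101.3, lat = 30.7), years = 20)
  expect_true(sh2$bearing_deg > 0 && sh2$bearing_deg < 90)
  expect_equal(sh2$direction, "NE")
  expect_equal(compass_sector(c(0, 44, 90, 180, 250, 320)),
               c("N", "NE", "E", "S", "W", "NW"))
})
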