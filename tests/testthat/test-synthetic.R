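test_that("stack generation is seeded, standardized, and mixes to known correlations", {
  s1 <- make_stack(n_layers = 3, nrows = 50, ncols = 50, corr_length = 4, seed = 21)
  s2 <- make_stack(n_layers = 3, nrows = 50, ncols = 50, corr_length = 4, seed = 21)
  expect_identical(s1$layers$bio1$values, s2$layers$bio1$values)  # determinism

  # identity mixing: inter-layer correlation within sampling error
  r <- pearson_matrix(s1)
  offdiag <- abs(r[upper.tri(r)])
  expect_lt(max(offdiag), 0.35)  # smoothed fields have few effective dof

  # duplicating a layer through the mixing matrix forces r ~ 1
  mix <- diag(3); mix[3, ] <- c(1, 0, 0)
  s3 <- make_stack(n_layers = 3, nrows = 50, ncols = 50, corr_length = 4,
                   mixing = mix, seed = 21)
  r3 <- pearson_matrix(s3)
  expect_equal(r3["bio1", "bio3"], 1, tolerance = 1e-9)

  # white noise (no smoothing): independence bound ~2/sqrt(n)
  w <- make_stack(n_layers = 2, nrows = 100, ncols = 100, corr_length = 0, seed = 5)
  rw <- pearson_matrix(w)
  expect_lt(abs(rw[1, 2]), 0.05)

  expect_error(make_stack(n_layers = 2, mixing = matrix(0, 2, 2)), "mixing")
  # per-layer standardization
  expect_equal(mean(s1$layers$bio2$values), 0, tolerance = 1e-12)
  expect_equal(sd(s1$layers$bio2$values), 1, tolerance = 1e-12)
})

test_that("truth surfaces realize the specified responses", {
  s <- make_stack(n_layers = 2, nrows = 30, ncols = 30, corr_length = 3, seed = 22)
  flat <- make_truth(s)
  expect_true(all(flat$values == 0.5))

  mono <- make_truth(s, linear = c(bio1 = 2))
  o <- order(s$layers$bio1$values)
  expect_true(all(diff(mono$values[o]) >= 0))

  # quadratic optimum at the stated center
  q <- make_truth(s, quadratic = c(bio1 = -3), quadratic_center = c(bio1 = 0.4))
  best <- which.max(q$values)
  x_at_best <- s$layers$bio1$values[best]
  x_near <- sort(abs(s$layers$bio1$values - 0.4))[1]
  expect_equal(abs(x_at_best - 0.4), x_near)  # argmax is the cell closest to 0.4

  expect_error(make_truth(s, linear = c(nope = 1)), "unknown layer")
})

test_that("occurrence sampling is truth-proportional, seeded, and exclusive", {
  s <- make_stack(n_layers = 1, nrows = 20, ncols = 20, corr_length = 2, seed = 23)
  # single-cell truth: the only possible draw
  v <- matrix(0, 20, 20); v[7, 9] <- 1
  spike <- new_raster(v, s$header$xll, s$header$yll, s$header$cellsize)
  occ1 <- sample_occurrences(spike, 1, seed = 3)
  expect_equal(lonlat_cell(spike, occ1$longitude, occ1$latitude),
               which(as.vector(v) == 1))

  truth <- make_truth(s, linear = c(bio1 = 2))
  occ <- sample_occurrences(truth, 200, seed = 4)
  occ_b <- sample_occurrences(truth, 200, seed = 4)
  expect_identical(occ, occ_b)
  # importance-sampling property: presences sit on better-than-average cells
  expect_gt(mean(truth$values[attr(occ, "cells")]), mean(truth$values))
  # without replacement: all cells distinct
  expect_equal(anyDuplicated(attr(occ, "cells")), 0)
  expect_error(sample_occurrences(truth, 1e6), "exceeds")
})

test_that("future shifts translate the suitable band predictably", {
  s <- make_stack(n_layers = 1, nrows = 40, ncols = 40, corr_length = 3, seed = 24)
  expect_identical(make_future(s, c(bio1 = 0))$layers$bio1$values,
                   s$layers$bio1$values)
  expect_error(make_future(s, c(zzz = 1)), "unknown layer")

  # pure latitudinal gradient: +delta moves the band delta/g degrees poleward
  h <- s$header
  lat <- matrix(rep(h$yll + (h$nrows:1 - 0.5) * h$cellsize, h$ncols), h$nrows, h$ncols)
  g <- -0.8  # temperature falls 0.8 units per degree northward
  grad <- raster_stack(list(bio1 = new_raster(g * (lat - mean(lat)), h$xll, h$yll, h$cellsize)))
  truth_now <- make_truth(grad, intercept = 2, quadratic = c(bio1 = -40))
  delta <- 0.2
  truth_fut <- make_truth(make_future(grad, c(bio1 = delta)),
                          intercept = 2, quadratic = c(bio1 = -40))
  c_now <- suitable_centroid(binarize_suitability(truth_now, 0.6))
  c_fut <- suitable_centroid(binarize_suitability(truth_fut, 0.6))
  expect_equal(c_fut[["lat"]] - c_now[["lat"]], delta / abs(g),
               tolerance = 0.5 * h$cellsize / (delta / abs(g)))

  # translation symmetry: gain ~ loss on an interior band
  cm <- change_map(binarize_suitability(truth_now, 0.6),
                   binarize_suitability(truth_fut, 0.6))
  st <- change_stats(cm)
  expect_equal(st$gain, st$loss, tolerance = 0.02)
})

test_that("the scenario wires stack, truth, presences and future together", {
  # steep gradient variant so the thermal band dominates the random field
  sc <- make_scenario(seed = 42, n_presence = 50, nrows = 40, ncols = 40,
                      n_layers = 5, lat_gradient = -3, warming = 0.9)
  expect_setequal(names(sc$stack$layers), paste0("bio", 1:5))
  expect_equal(nrow(sc$occurrences), 50)
  tv <- sc$truth$values
  expect_true(all(tv >= 0 & tv <= 1))
  # warming raises suitability where the positive-coefficient layer rises
  expect_gt(mean(sc$truth_future$values), mean(sc$truth$values))
  # and pushes the suitable band northward along the gradient
  c_now <- suitable_centroid(binarize_suitability(sc$truth, 0.5))
  c_fut <- suitable_centroid(binarize_suitability(sc$truth_future, 0.5))
  expect_gt(c_fut[["lat"]], c_now[["lat"]])
})
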