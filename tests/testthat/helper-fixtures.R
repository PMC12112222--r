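# Shared fixtures, built once per test run.

# Small landscape: 40x40 cells, 3 layers, 80 presences.
tiny <- make_scenario(seed = 7, n_presence = 80, nrows = 40, ncols = 40,
                      n_layers = 3, corr_length = 4)
tiny_bg_cells <- sample_background(tiny$stack, 800, seed = 99)
tiny_pres_X <- stack_values(tiny$stack, attr(tiny$occurrences, "cells"))
tiny_bg_X <- stack_values(tiny$stack, tiny_bg_cells)

# Independent penalized-maxent objective used by optimizer oracles; written
# from the definition, not via the package's fitting path.
r_maxent_objective <- function(Fp, Fb, lambda) {
  function(beta) {
    eta_p <- Fp %*% beta
    eta_b <- Fb %*% beta
    -mean(eta_p) + log(mean(exp(eta_b))) + sum(lambda * abs(beta))
  }
}

# Independent haversine for thinning/centroid oracles (spherical law of
# cosines variant, same mean radius).
oracle_dist_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  d <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  6371.0088 * acos(pmin(1, pmax(-1, d)))
}

# A deterministic little raster for I/O tests.
demo_raster <- function(vals = matrix(1:9, 3, 3, byrow = TRUE),
                        xll = 100, yll = 25, cs = 0.5) {
  new_raster(vals, xll, yll, cs)
}
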