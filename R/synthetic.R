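#' Generate a climate-like synthetic raster stack
#'
#' Independent Gaussian random fields are produced by convolving seeded
#' white noise with a Gaussian smoothing kernel (separable row/column
#' passes, edge-normalized), linearly mixed by the rows of `mixing` to
#' induce known pairwise correlations, and standardized per layer (mean 0,
#' SD 1 over the grid).
#'
#' @param n_layers number of layers.
#' @param nrows,ncols grid size in cells.
#' @param corr_length spatial autocorrelation length (kernel SD) in cells.
#' @param mixing `n_layers x n_layers` mixing matrix applied to the
#'   independent fields (`NULL` = identity); every row must be finite with
#'   positive norm.
#' @param seed RNG seed; identical seeds give bit-identical stacks.
#' @param xll,yll,cellsize georeferencing of the grid (defaults place a
#'   2.5 arc-min grid in subtropical East Asia).
#' @param layer_names names for the layers (default `bio1..bioN`).
#' @return an `sdm_stack`.
#' @export
make_stack <- function(n_layers = 5, nrows = 120, ncols = 120, corr_length = 8,
                       mixing = NULL, seed = 1, xll = 100, yll = 22,
                       cellsize = 2.5 / 60, layer_names = NULL) {
  stopifnot(n_layers >= 1)
  if (is.null(mixing)) mixing <- diag(n_layers)
  mixing <- as.matrix(mixing)
  if (!all(is.finite(mixing)) || any(rowSums(mixing^2) <= 0))
    stop("mixing matrix must be finite with positive row norms")
  if (nrow(mixing) != n_layers || ncol(mixing) != n_layers)
    stop("mixing matrix must be n_layers x n_layers")
  if (is.null(layer_names)) layer_names <- paste0("bio", seq_len(n_layers))

  set.seed(seed)
  smooth_field <- function() {
    z <- matrix(rnorm(nrows * ncols), nrows, ncols)
    if (corr_length > 0) {
      half <- max(1L, ceiling(3 * corr_length))
      g <- exp(-0.5 * ((-half:half) / corr_length)^2)
      W <- function(n) {
        M <- outer(seq_len(n), seq_len(n), function(i, k) {
          d <- abs(i - k)
          ifelse(d <= half, exp(-0.5 * (d / corr_length)^2), 0)
        })
        M / rowSums(M)
      }
      z <- W(nrows) %*% z %*% t(W(ncols))
    }
    z
  }
  fields <- lapply(seq_len(n_layers), function(i) smooth_field())
  layers <- lapply(seq_len(n_layers), function(i) {
    v <- Reduce(`+`, Map(`*`, fields, mixing[i, ]))
    v <- (v - mean(v)) / sd(v)
    new_raster(v, xll, yll, cellsize)
  })
  names(layers) <- layer_names
  raster_stack(layers)
}

#' True suitability surface from known responses
#'
#' Builds `truth = plogis(lp)` with
#' `lp = intercept + sum linear_i * x_i + sum quad_i * (x_i - center_i)^2 +
#' hinge terms`, so the generating responses are known exactly and
#' recoverable by the fitting engine.
#'
#' @param stack an `sdm_stack`.
#' @param intercept scalar offset.
#' @param linear named coefficient vector (layer names).
#' @param quadratic named coefficient vector; `quadratic_center` gives the
#'   optimum location per layer (default 0), so a negative coefficient puts
#'   the truth argmax at the center.
#' @param quadratic_center named centers for the quadratic terms.
#' @param hinge optional list of `list(layer=, knot=, coef=, direction=
#'   "forward"|"reverse")` terms, `max(0, x - knot)` or `max(0, knot - x)`.
#' @return `sdm_raster` of true suitability in \[0, 1\].
#' @export
make_truth <- function(stack, intercept = 0, linear = NULL, quadratic = NULL,
                       quadratic_center = NULL, hinge = NULL) {
  known <- names(stack$layers)
  used <- c(names(linear), names(quadratic),
            vapply(hinge, function(h) h$layer, character(1)))
  bad <- setdiff(used, known)
  if (length(bad)) stop("unknown layer name(s) in truth terms: ", paste(bad, collapse = ", "))
  h <- stack$header
  lp <- matrix(intercept, h$nrows, h$ncols)
  for (v in names(linear)) lp <- lp + linear[[v]] * stack$layers[[v]]$values
  for (v in names(quadratic)) {
    ctr <- if (!is.null(quadratic_center) && v %in% names(quadratic_center))
      quadratic_center[[v]] else 0
    lp <- lp + quadratic[[v]] * (stack$layers[[v]]$values - ctr)^2
  }
  for (hg in hinge) {
    x <- stack$layers[[hg$layer]]$values
    term <- if (identical(hg$direction, "reverse")) pmax(0, hg$knot - x) else pmax(0, x - hg$knot)
    lp <- lp + hg$coef * term
  }
  mask <- Reduce(`&`, lapply(stack$layers, raster_mask))
  lp[!mask] <- NA_real_
  new_raster(plogis(lp), h$xll, h$yll, h$cellsize, h$nodata)
}

#' Sample presence records proportional to a truth surface
#'
#' Cells are drawn without replacement with probability proportional to
#' the truth (optionally multiplied by a sampling-bias field); one record
#' is placed at each drawn cell's center.
#'
#' @param truth `sdm_raster` of suitability in \[0, 1\].
#' @param n number of records (<= number of unmasked cells).
#' @param bias optional `sdm_raster` of nonnegative sampling weights.
#' @param seed RNG seed.
#' @param name taxon label for the records.
#' @return occurrence data.frame (`name`, `longitude`, `latitude`) with the
#'   drawn cell indices as attribute `"cells"`.
#' @export
sample_occurrences <- function(truth, n, bias = NULL, seed = 1,
                               name = "synthetic_taxon") {
  stopifnot(n >= 1)
  cells <- which(!is.na(as.vector(truth$values)))
  if (n > length(cells)) stop("n exceeds the number of unmasked cells")
  w <- truth$values[cells]
  if (!is.null(bias)) w <- w * bias$values[cells]
  set.seed(seed)
  picked <- sample(cells, n, prob = w)
  ll <- cell_lonlat(truth, picked)
  out <- data.frame(name = name, longitude = ll$lon, latitude = ll$lat,
                    stringsAsFactors = FALSE)
  attr(out, "cells") <- picked
  out
}

#' Shifted "future" stack
#'
#' Adds named per-layer constants to a stack (e.g. uniform warming on a
#' temperature layer); layers without a delta are copied unchanged. Under
#' unchanged truth coefficients, a delta on a layer with a latitudinal
#' gradient translates the suitable band along the gradient.
#'
#' @param stack an `sdm_stack`.
#' @param deltas named numeric vector of additive shifts.
#' @return an `sdm_stack` sharing the input header.
#' @export
make_future <- function(stack, deltas) {
  bad <- setdiff(names(deltas), names(stack$layers))
  if (length(bad)) stop("deltas name unknown layer(s): ", paste(bad, collapse = ", "))
  h <- stack$header
  layers <- lapply(names(stack$layers), function(v) {
    d <- if (v %in% names(deltas)) deltas[[v]] else 0
    new_raster(stack$layers[[v]]$values + d, h$xll, h$yll, h$cellsize, h$nodata)
  })
  names(layers) <- names(stack$layers)
  raster_stack(layers)
}

#' Default synthetic study scenario
#'
#' The fixed reference fixture for recovery and end-to-end tests: a
#' 120 x 120-cell, 2.5 arc-min, 5-layer stack (autocorrelation length 8
#' cells, mild collinearity between two layer pairs), a linear + quadratic
#' truth with the temperature-like layer `bio1` carrying a latitudinal
#' gradient, 200 presence records sampled from the truth, and a uniformly
#' warmed future stack whose truth band sits poleward (north) of the
#' current one.
#'
#' @param seed master RNG seed (default 42).
#' @param n_presence presence records to sample.
#' @param nrows,ncols,n_layers,corr_length grid generator parameters.
#' @param warming additive future shift on `bio1`, in layer SD units.
#' @param lat_gradient `bio1` trend per degree latitude (negative = colder
#'   northward).
#' @return list: `stack`, `truth`, `occurrences`, `future`, `truth_future`,
#'   and `config` (all generator parameters, including the truth
#'   coefficients).
#' @export
make_scenario <- function(seed = 42, n_presence = 200, nrows = 120, ncols = 120,
                          n_layers = 5, corr_length = 8, warming = 0.75,
                          lat_gradient = -0.5) {
  mixing <- diag(n_layers)
  if (n_layers >= 4) { mixing[4, 1] <- 0.6; mixing[4, 4] <- 0.55 }
  if (n_layers >= 5) { mixing[5, 2] <- 0.5; mixing[5, 5] <- 0.7 }
  stack <- make_stack(n_layers = n_layers, nrows = nrows, ncols = ncols,
                      corr_length = corr_length, mixing = mixing, seed = seed)
  # impose a latitudinal gradient on the temperature-like layer
  h <- stack$header
  lat_mid <- h$yll + h$nrows * h$cellsize / 2
  lat <- matrix(rep(h$yll + (h$nrows:1 - 0.5) * h$cellsize, h$ncols), h$nrows, h$ncols)
  b1 <- stack$layers$bio1$values + lat_gradient * (lat - lat_mid)
  stack$layers$bio1 <- new_raster(b1, h$xll, h$yll, h$cellsize, h$nodata)

  truth_terms <- list(intercept = 0.25, linear = c(bio1 = 1.4),
                      quadratic = c(bio2 = -0.8))
  truth <- make_truth(stack, intercept = truth_terms$intercept,
                      linear = truth_terms$linear, quadratic = truth_terms$quadratic)
  occ <- sample_occurrences(truth, n_presence, seed = seed + 1)
  future <- make_future(stack, c(bio1 = warming))
  truth_future <- make_truth(future, intercept = truth_terms$intercept,
                             linear = truth_terms$linear,
                             quadratic = truth_terms$quadratic)
  list(stack = stack, truth = truth, occurrences = occ, future = future,
       truth_future = truth_future,
       config = list(seed = seed, n_presence = n_presence, nrows = nrows,
                     ncols = ncols, n_layers = n_layers,
                     corr_length = corr_length, mixing = mixing,
                     warming = warming, lat_gradient = lat_gradient,
                     truth = truth_terms))
}
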