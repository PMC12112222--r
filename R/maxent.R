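#' Fit an L1-penalized maxent model
#'
#' Estimates the maximum-entropy (Gibbs) distribution over background cells
#' subject to presence feature constraints, by minimizing the penalized
#' negative log-likelihood
#' \deqn{-\frac{1}{m}\sum_{presence}\eta(x) + \log \bar Z + \sum_j \lambda_j |\beta_j|}
#' with \eqn{\eta = \beta \cdot f(x)}, \eqn{\bar Z} the background mean of
#' \eqn{e^\eta}, and \eqn{\lambda_j = rm \cdot} the per-feature default
#' regularization weight. The optimizer is cyclic coordinate descent with
#' local Newton steps and soft-thresholding (compiled); the objective is
#' convex, equals 0 at \eqn{\beta = 0}, and the regularized training gain is
#' its negative at the optimum.
#'
#' @param presence numeric matrix/data.frame of layer values at presence
#'   points (named columns; >= 5 rows).
#' @param background layer values at background points (same columns).
#' @param fc feature-class code (see [build_features()]).
#' @param rm regularization multiplier (> 0).
#' @param n_knots hinge/threshold knots per layer.
#' @param max_iter maximum number of coordinate-descent sweeps.
#' @param tol convergence tolerance on the objective decrease per sweep.
#' @return an object of class `maxent_model`: feature set, coefficients
#'   `beta`, penalties `lambda`, background normalizer `Zmean`, entropy `H`
#'   of the raw distribution, regularized training gain `gain`, per-feature
#'   path contributions `contrib`, background layer means `bg_means`, and
#'   convergence metadata.
#' @export
fit_maxent <- function(presence, background, fc = "LQ", rm = 1, n_knots = 50,
                       max_iter = 5000, tol = 1e-5) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  if (nrow(presence) < 5) stop("need at least 5 presence records")
  if (rm <= 0) stop("regularization multiplier must be > 0")
  if (!identical(colnames(presence), colnames(background)))
    stop("presence and background must share the same layer columns")
  fs <- build_features(background, fc, n_knots = n_knots)
  Fp <- evaluate_features(fs, presence)
  Fb <- evaluate_features(fs, background)
  lambda <- feature_penalties(fs, Fp, rm)
  fit <- .cd_maxent(Fp, Fb, lambda, as.integer(max_iter), tol)
  beta <- as.numeric(fit$beta)

  eta_b <- drop(Fb %*% beta)
  N <- nrow(Fb)
  Zmean <- mean(exp(eta_b))
  q <- exp(eta_b) / (N * Zmean)
  H <- -sum(ifelse(q > 0, q * log(q), 0))

  structure(list(
    features = fs, beta = setNames(beta, fs$defs$id), lambda = lambda,
    rm = rm, fc = fs$fc, layer_names = fs$layer_names,
    n_presence = nrow(Fp), n_background = N,
    Zmean = Zmean, H = H,
    gain = fit$gain, objective = fit$objective,
    contrib = setNames(as.numeric(fit$contrib), fs$defs$id),
    bg_means = colMeans(background),
    iterations = fit$iterations, converged = fit$converged),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> fc=%s rm=%g | %d features (%d nonzero) | gain %.4f\n",
              x$fc, x$rm, length(x$beta), sum(x$beta != 0), x$gain))
  cat(sprintf("  %d presences vs %d background; %s after %d sweeps\n",
              x$n_presence, x$n_background,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Regularized training gain
#'
#' Penalized log-likelihood improvement over the uniform null model
#' (which has gain 0); non-negative at the optimum.
#'
#' @param model a fitted `maxent_model`.
#' @return the gain.
#' @export
training_gain <- function(model) model$gain

# eta for a matrix of layer values (clamped to training range)
model_eta <- function(model, X) {
  F_ <- evaluate_features(model$features, as.matrix(X))
  drop(F_ %*% model$beta)
}

#' Predict suitability from a maxent model
#'
#' `raw` output is the Gibbs density normalized to sum 1 over the training
#' background; `logistic` output is `raw * e^H / (1 + raw * e^H)` (entropy
#' formulation, default prevalence 0.5), bounded in \[0, 1\]. Layer values
#' are clamped to the training range before feature scaling.
#'
#' @param object a fitted `maxent_model`.
#' @param newdata an `sdm_stack` (returns an `sdm_raster`) or a matrix of
#'   layer values (returns a vector).
#' @param type `"logistic"` (default), `"raw"`, or `"eta"` (the linear
#'   predictor).
#' @param ... unused.
#' @return raster or numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata, type = c("logistic", "raw", "eta"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "sdm_stack")) {
    missing_layers <- setdiff(object$layer_names, names(newdata$layers))
    if (length(missing_layers))
      stop("stack lacks model layer(s): ", paste(missing_layers, collapse = ", "))
    cells <- valid_cells(newdata)
    X <- stack_values(newdata, cells)[, object$layer_names, drop = FALSE]
    p <- predict(object, X, type = type)
    h <- newdata$header
    out <- matrix(NA_real_, h$nrows, h$ncols)
    out[cells] <- p
    return(new_raster(out, h$xll, h$yll, h$cellsize, h$nodata))
  }
  X <- as.matrix(newdata)[, object$layer_names, drop = FALSE]
  eta <- model_eta(object, X)
  switch(type,
    eta = eta,
    raw = exp(eta) / (object$n_background * object$Zmean),
    logistic = plogis(eta + object$H - log(object$n_background * object$Zmean)))
}

#' Serialize a maxent model to JSON
#'
#' Writes features (definitions, knots, scalings), coefficients, penalties,
#' normalizer, entropy and configuration — sufficient for bit-reproducible
#' prediction via [read_maxent_model()].
#'
#' @param model a `maxent_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  payload <- list(
    package = "maxsdm", class = "maxent_model",
    fc = model$fc, rm = model$rm, n_knots = model$features$n_knots,
    layer_names = model$layer_names,
    defs = model$features$defs,
    scaling = cbind(id = rownames(model$features$scaling), model$features$scaling),
    layer_range = cbind(layer = rownames(model$features$layer_range),
                        as.data.frame(model$features$layer_range)),
    beta = unclass(model$beta), lambda = model$lambda,
    n_presence = model$n_presence, n_background = model$n_background,
    Zmean = model$Zmean, H = model$H, gain = model$gain,
    objective = model$objective, contrib = unclass(model$contrib),
    bg_means = as.list(model$bg_means),
    iterations = model$iterations, converged = model$converged)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a serialized maxent model
#'
#' @param path file written by [write_maxent_model()].
#' @return a `maxent_model`.
#' @export
read_maxent_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  lr <- as.matrix(p$layer_range[, c("min", "max")])
  rownames(lr) <- p$layer_range$layer
  fs <- structure(list(
    defs = p$defs,
    scaling = data.frame(fmin = p$scaling$fmin, fmax = p$scaling$fmax,
                         row.names = p$scaling$id),
    layer_range = lr, layer_names = p$layer_names,
    fc = p$fc, n_knots = p$n_knots), class = "maxent_features")
  structure(list(
    features = fs, beta = setNames(as.numeric(p$beta), p$defs$id),
    lambda = as.numeric(p$lambda), rm = p$rm, fc = p$fc,
    layer_names = p$layer_names, n_presence = p$n_presence,
    n_background = p$n_background, Zmean = p$Zmean, H = p$H,
    gain = p$gain, objective = p$objective,
    contrib = setNames(as.numeric(p$contrib), p$defs$id),
    bg_means = unlist(p$bg_means),
    iterations = p$iterations, converged = p$converged),
    class = "maxent_model")
}
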