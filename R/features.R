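#' Build a maxent feature set
#'
#' Expands environmental layers into the classic maxent feature classes:
#' Linear, Quadratic, Product (all pairwise), forward/reverse Hinge and
#' Threshold (step) features with knots at empirical background quantiles.
#' Every feature is scaled so that its values over the background lie in
#' \[0, 1\]; linear/quadratic/product features are min-max scaled on the
#' background, hinge and threshold features are \[0, 1\] by construction.
#'
#' @param bg numeric matrix of background layer values (columns named by
#'   layer).
#' @param fc feature-class code: any subset string of `L`, `Q`, `H`, `P`,
#'   `T`, e.g. `"LQ"`, `"LQHPT"`. `H` generates both forward and reverse
#'   hinges.
#' @param n_knots number of interior quantile knots per layer for hinge and
#'   threshold features.
#' @return an object of class `maxent_features`: `defs` (data.frame with
#'   `id`, `kind`, `var1`, `var2`, `knot`), `scaling` (per-feature min/max),
#'   `layer_range` (per-layer training min/max used for clamping),
#'   `layer_names`, `fc`, `n_knots`.
#' @export
build_features <- function(bg, fc, n_knots = 50) {
  bg <- as.matrix(bg)
  if (is.null(colnames(bg))) colnames(bg) <- paste0("x", seq_len(ncol(bg)))
  letters_fc <- unique(strsplit(toupper(fc), "")[[1]])
  bad <- setdiff(letters_fc, c("L", "Q", "H", "P", "T"))
  if (length(bad)) stop("unknown feature-class letter(s): ", paste(bad, collapse = ", "))
  vars <- colnames(bg)
  layer_range <- t(apply(bg, 2, range, na.rm = TRUE))
  colnames(layer_range) <- c("min", "max")

  defs <- list()
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_) {
    id <- switch(kind,
      linear = paste0("L:", var1),
      quadratic = paste0("Q:", var1),
      product = paste0("P:", var1, ":", var2),
      forward_hinge = sprintf("HF:%s:%.8g", var1, knot),
      reverse_hinge = sprintf("HR:%s:%.8g", var1, knot),
      threshold = sprintf("T:%s:%.8g", var1, knot))
    defs[[length(defs) + 1]] <<- data.frame(
      id = id, kind = kind, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  }
  if ("L" %in% letters_fc) for (v in vars) add("linear", v)
  if ("Q" %in% letters_fc) for (v in vars) add("quadratic", v)
  if ("P" %in% letters_fc && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1))
      for (j in seq(i + 1, length(vars))) add("product", vars[i], vars[j])
  }
  if (any(c("H", "T") %in% letters_fc)) {
    probs <- seq_len(n_knots) / (n_knots + 1)
    for (v in vars) {
      ks <- unique(as.numeric(quantile(bg[, v], probs, na.rm = TRUE, names = FALSE)))
      lo <- layer_range[v, "min"]; hi <- layer_range[v, "max"]
      if ("H" %in% letters_fc) {
        for (k in ks[ks < hi]) add("forward_hinge", v, knot = k)
        for (k in ks[ks > lo]) add("reverse_hinge", v, knot = k)
      }
      if ("T" %in% letters_fc) for (k in ks[ks < hi & ks > lo]) add("threshold", v, knot = k)
    }
  }
  if (!length(defs)) stop("feature class '", fc, "' yields no features for these layers")
  defs <- do.call(rbind, defs)

  fs <- structure(list(defs = defs, scaling = NULL, layer_range = layer_range,
                       layer_names = vars, fc = paste(letters_fc, collapse = ""),
                       n_knots = n_knots), class = "maxent_features")
  Fraw <- eval_features_raw(fs, bg, clamp = FALSE)
  fmin <- apply(Fraw, 2, min)
  fmax <- apply(Fraw, 2, max)
  keep <- fmax > fmin
  if (!any(keep)) stop("degenerate feature set: every feature is constant over the background")
  fs$defs <- defs[keep, , drop = FALSE]
  rownames(fs$defs) <- NULL
  fs$scaling <- data.frame(fmin = fmin[keep], fmax = fmax[keep], row.names = fs$defs$id)
  fs
}

# Raw (unscaled) feature evaluation; hinge/threshold are already in [0,1].
eval_features_raw <- function(fs, X, clamp = TRUE) {
  X <- as.matrix(X)
  if (clamp) {
    for (v in fs$layer_names) {
      lr <- fs$layer_range[v, ]
      X[, v] <- pmin(pmax(X[, v], lr[["min"]]), lr[["max"]])
    }
  }
  d <- fs$defs
  out <- matrix(NA_real_, nrow(X), nrow(d), dimnames = list(NULL, d$id))
  lr <- fs$layer_range
  for (j in seq_len(nrow(d))) {
    kind <- d$kind[j]; v <- d$var1[j]; k <- d$knot[j]
    out[, j] <- switch(kind,
      linear = X[, v],
      quadratic = X[, v]^2,
      product = X[, v] * X[, d$var2[j]],
      forward_hinge = pmax(0, (X[, v] - k)) / (lr[v, "max"] - k),
      reverse_hinge = pmax(0, (k - X[, v])) / (k - lr[v, "min"]),
      threshold = as.numeric(X[, v] > k))
  }
  out
}

#' Evaluate a feature set on layer values
#'
#' Layer values are clamped to the training range recorded in the feature
#' set (standard maxent projection behaviour), then transformed and scaled
#' to the training \[0, 1\] range.
#'
#' @param fs a `maxent_features` object.
#' @param X numeric matrix of layer values with the feature set's layers as
#'   named columns.
#' @param clamp clamp layers to the training range first (default `TRUE`).
#' @return numeric feature matrix, one column per feature.
#' @export
evaluate_features <- function(fs, X, clamp = TRUE) {
  Fraw <- eval_features_raw(fs, X, clamp = clamp)
  fmin <- fs$scaling$fmin; fmax <- fs$scaling$fmax
  sweep(sweep(Fraw, 2, fmin, "-"), 2, fmax - fmin, "/")
}

# Published maxent default regularization tables: class-specific base beta
# interpolated against the presence sample size (flat beyond the table ends).
reg_tables <- list(
  linear = list(n = c(10, 30, 100), beta = c(1.0, 0.2, 0.05)),
  quadratic = list(n = c(0, 10, 17, 30, 100), beta = c(1.3, 0.8, 0.5, 0.25, 0.05)),
  product = list(n = c(0, 10, 17, 30, 100), beta = c(2.6, 1.6, 0.9, 0.55, 0.05)),
  hinge = list(n = c(0, 1), beta = c(0.5, 0.5)),
  threshold = list(n = c(0, 100), beta = c(2.0, 1.0)))

#' Default per-class regularization base weight
#'
#' Interpolates the published maxent default tables against the number of
#' presence records; hinge features use the constant 0.5. Values are flat
#' beyond the tabulated sample sizes.
#'
#' @param kind one of `linear`, `quadratic`, `product`, `forward_hinge`,
#'   `reverse_hinge`, `hinge`, `threshold` (vectorized).
#' @param n_presence presence sample size (>= 2).
#' @return base regularization weight(s).
#' @export
default_reg_scale <- function(kind, n_presence) {
  stopifnot(n_presence >= 2)
  kind <- ifelse(kind %in% c("forward_hinge", "reverse_hinge"), "hinge", kind)
  vapply(kind, function(k) {
    tab <- reg_tables[[k]]
    if (is.null(tab)) stop("unknown feature kind: ", k)
    stats::approx(tab$n, tab$beta, xout = n_presence, rule = 2)$y
  }, numeric(1), USE.NAMES = FALSE)
}

# Per-feature L1 penalty weights: lambda_j = rm * base(class, m) * sd_j / sqrt(m),
# with the presence-sample SD of the scaled feature floored at 1e-3 so that
# near-constant features still carry a positive penalty.
feature_penalties <- function(fs, Fp, rm) {
  m <- nrow(Fp)
  base <- default_reg_scale(fs$defs$kind, m)
  sds <- pmax(apply(Fp, 2, sd), 1e-3)
  rm * base * sds / sqrt(m)
}
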