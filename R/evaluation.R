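#' Presence-vs-background rank AUC
#'
#' Mann-Whitney statistic: the probability that a random presence
#' prediction exceeds a random background prediction, counting ties as 1/2.
#'
#' @param pred_presence,pred_background prediction vectors (nonempty).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pred_presence, pred_background) {
  np <- length(pred_presence); nb <- length(pred_background)
  stopifnot(np > 0, nb > 0)
  r <- rank(c(pred_presence, pred_background))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' True Skill Statistic at a threshold
#'
#' Sensitivity + specificity - 1 with presence predicted iff
#' `pred >= threshold`.
#'
#' @param pred_presence predictions at presences.
#' @param pred_background predictions at (pseudo-)absences.
#' @param threshold cutoff in \[0, 1\].
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(pred_presence, pred_background, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  sens <- mean(pred_presence >= threshold)
  spec <- mean(pred_background < threshold)
  sens + spec - 1
}

#' Qualitative AUC band
#'
#' Left-closed bands on the conventional scale: \[0, 0.5) fail,
#' \[0.5, 0.7) poor, \[0.7, 0.8) fair, \[0.8, 0.9) good, \[0.9, 1\]
#' excellent.
#'
#' @param auc AUC value(s).
#' @return character band label(s).
#' @export
auc_band <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  lab <- c("fail", "poor", "fair", "good", "excellent")
  lab[findInterval(auc, c(0, 0.5, 0.7, 0.8, 0.9))]
}

#' Jackknife variable importance
#'
#' For each variable, refits the model with only that variable
#' (`rtg_alone`) and with all variables but that one (`gain_without`),
#' under the same feature class and regularization multiplier. A refit
#' failure flags the entry (`NA`) and leaves the others unaffected.
#'
#' @param presence,background layer-value matrices (named columns, >= 2
#'   variables).
#' @param fc,rm,n_knots,max_iter,tol passed to [fit_maxent()].
#' @return data.frame (`variable`, `rtg_alone`, `gain_without`) with the
#'   full-model gain as attribute `"gain_full"`.
#' @export
jackknife_importance <- function(presence, background, fc = "LQ", rm = 1,
                                 n_knots = 50, max_iter = 5000, tol = 1e-5) {
  vars <- colnames(background)
  stopifnot(length(vars) >= 2)
  safe_gain <- function(cols) {
    tryCatch(training_gain(fit_maxent(presence[, cols, drop = FALSE],
                                      background[, cols, drop = FALSE],
                                      fc = fc, rm = rm, n_knots = n_knots,
                                      max_iter = max_iter, tol = tol)),
             error = function(e) NA_real_)
  }
  out <- data.frame(
    variable = vars,
    rtg_alone = vapply(vars, function(v) safe_gain(v), numeric(1)),
    gain_without = vapply(vars, function(v) safe_gain(setdiff(vars, v)), numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "gain_full") <- safe_gain(vars)
  rownames(out) <- NULL
  out
}

#' Percent contribution from the fitting path
#'
#' Credits each coordinate-descent step's objective improvement to the
#' variable owning the updated feature (product features split their credit
#' equally between their two variables) and normalizes to 100%.
#'
#' @param model a `maxent_model` fitted by [fit_maxent()] (which records the
#'   path).
#' @return named percentage vector summing to 100.
#' @export
percent_contribution <- function(model) {
  if (is.null(model$contrib))
    stop("model carries no fitting path; use permutation_importance() instead")
  d <- model$features$defs
  acc <- setNames(numeric(length(model$layer_names)), model$layer_names)
  for (j in seq_len(nrow(d))) {
    cj <- model$contrib[[j]]
    if (d$kind[j] == "product") {
      acc[d$var1[j]] <- acc[d$var1[j]] + cj / 2
      acc[d$var2[j]] <- acc[d$var2[j]] + cj / 2
    } else {
      acc[d$var1[j]] <- acc[d$var1[j]] + cj
    }
  }
  total <- sum(acc)
  if (total <= 0) {
    warning("no objective improvement recorded; contributions undefined, returning zeros")
    return(acc)
  }
  100 * acc / total
}

#' Permutation importance
#'
#' For each variable, permutes its values jointly across presence and
#' background rows (maxent convention), recomputes the training AUC, and
#' reports the normalized AUC drop (negative drops floored at 0), averaged
#' over `n_rep` permutations.
#'
#' @param model a fitted `maxent_model`.
#' @param presence,background training layer-value matrices.
#' @param seed permutation seed.
#' @param n_rep number of permutation repeats to average.
#' @return named percentage vector summing to 100 (or zeros, with a
#'   warning, when no variable matters).
#' @export
permutation_importance <- function(model, presence, background, seed = 1, n_rep = 10) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  base_auc <- rank_auc(predict(model, presence), predict(model, background))
  np <- nrow(presence)
  all_X <- rbind(presence, background)
  set.seed(seed)
  drops <- vapply(model$layer_names, function(v) {
    mean(vapply(seq_len(n_rep), function(r) {
      Xp <- all_X
      Xp[, v] <- Xp[sample.int(nrow(Xp)), v]
      base_auc - rank_auc(predict(model, Xp[seq_len(np), , drop = FALSE]),
                          predict(model, Xp[-seq_len(np), , drop = FALSE]))
    }, numeric(1)))
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) <= 0) {
    warning("no AUC drop under any permutation; importances undefined, returning zeros")
    return(drops)
  }
  100 * drops / sum(drops)
}

#' Marginal response curve
#'
#' Varies one variable across its training range at fixed other-variable
#' background means and returns the logistic response; the argmax is
#' attached as an attribute.
#'
#' @param model a fitted `maxent_model`.
#' @param variable layer name.
#' @param n number of grid points.
#' @return data.frame (`value`, `logistic`) with attribute `"argmax"`.
#' @export
response_curve <- function(model, variable, n = 101) {
  if (!variable %in% model$layer_names) stop("variable not in model: ", variable)
  lr <- model$features$layer_range[variable, ]
  grid <- seq(lr[["min"]], lr[["max"]], length.out = n)
  X <- matrix(rep(model$bg_means[model$layer_names], each = n), nrow = n,
              dimnames = list(NULL, model$layer_names))
  X[, variable] <- grid
  y <- predict(model, X, type = "logistic")
  out <- data.frame(value = grid, logistic = y)
  attr(out, "argmax") <- grid[which.max(y)]
  out
}

#' Threshold crossings of a response curve
#'
#' Linear interpolation between grid points; used to read off
#' suitable-survival limits (curve = threshold) from response curves.
#'
#' @param curve data.frame from [response_curve()].
#' @param level the logistic level to intersect.
#' @return numeric vector of variable values where the curve crosses
#'   `level` (empty when it never does).
#' @export
curve_crossings <- function(curve, level) {
  x <- curve$value; y <- curve$logistic - level
  s <- which(y[-1] * y[-length(y)] < 0)
  cross <- x[s] + (x[s + 1] - x[s]) * (-y[s]) / (y[s + 1] - y[s])
  sort(unique(c(cross, x[y == 0])))
}
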