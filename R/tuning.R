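#' Checkerboard-2 spatial partition
#'
#' Assigns points to four cross-validation groups by two nested
#' checkerboards anchored at the grid origin: a fine board with block edge
#' `agg[1]` cells gives bit B by (block col + block row) parity, a coarse
#' board with block edge `agg[1] * agg[2]` cells gives bit A; the group is
#' `2A + B + 1`. Deterministic given the header.
#'
#' @param lon,lat point coordinates, degrees.
#' @param header raster header (or `sdm_raster`/`sdm_stack`) anchoring the
#'   boards.
#' @param agg two aggregation factors (integers >= 1).
#' @return integer group ids in 1..4.
#' @export
checkerboard2 <- function(lon, lat, header, agg = c(10, 2)) {
  h <- if (is.list(header) && !is.null(header$header)) header$header else header
  stopifnot(length(agg) == 2, all(agg >= 1))
  col <- floor((lon - h$xll) / h$cellsize)
  row <- floor((lat - h$yll) / h$cellsize)
  fine <- agg[1]; coarse <- agg[1] * agg[2]
  bitB <- (floor(col / fine) + floor(row / fine)) %% 2
  bitA <- (floor(col / coarse) + floor(row / coarse)) %% 2
  as.integer(2 * bitA + bitB + 1)
}

#' 10th-percentile training omission rate
#'
#' The threshold is the training-presence prediction that excludes the
#' lowest 10% of training predictions (ceiling index convention: with `n`
#' training presences, the `ceiling(0.1 n)` smallest values are excluded and
#' the threshold is the next order statistic). The rate is the fraction of
#' test presences strictly below that threshold.
#'
#' @param train_pred predictions at training presences (>= 10 values).
#' @param test_pred predictions at test presences.
#' @return omission rate in \[0, 1\].
#' @export
or10 <- function(train_pred, test_pred) {
  n <- length(train_pred)
  stopifnot(n >= 10)
  k <- ceiling(0.1 * n)
  thr <- sort(train_pred)[min(k + 1, n)]
  mean(test_pred < thr)
}

#' Sample-size-corrected AIC of a maxent model
#'
#' The raw distribution is standardized to sum 1 over all jointly valid
#' landscape cells (Warren-Seifert convention); the log-likelihood is the
#' sum of log standardized values at the presence cells; `k` is the number
#' of nonzero coefficients. `AICc = 2k - 2lnL + 2k(k+1)/(n-k-1)`, undefined
#' (`NA`) when `k >= n - 1`.
#'
#' @param model a fitted `maxent_model`.
#' @param stack the landscape `sdm_stack`.
#' @param presence_cells linear cell indices of the presences; records on
#'   masked cells are excluded with a warning.
#' @return the AICc, or `NA` when undefined.
#' @export
aicc_maxent <- function(model, stack, presence_cells) {
  cells <- valid_cells(stack)
  ok <- presence_cells %in% cells
  if (!all(ok)) {
    warning(sum(!ok), " presence record(s) on masked cells excluded from AICc")
    presence_cells <- presence_cells[ok]
  }
  n <- length(presence_cells)
  k <- sum(model$beta != 0)
  if (k >= n - 1) return(NA_real_)
  X <- stack_values(stack, cells)[, model$layer_names, drop = FALSE]
  eta <- model_eta(model, X)
  # log of exp(eta)/sum(exp(eta)), computed stably
  mx <- max(eta)
  log_p <- eta - mx - log(sum(exp(eta - mx)))
  lnL <- sum(log_p[match(presence_cells, cells)])
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Tune feature classes and regularization multipliers
#'
#' Grid search over feature-class codes and regularization multipliers
#' (7 x 8 = 56 combinations by default). For each combination, 4-fold
#' spatially partitioned (checkerboard-2) train/test metrics are averaged
#' (training/testing AUC, their difference, 10th-percentile omission rate),
#' a full-data fit supplies the nonzero-coefficient count and AICc, and the
#' combination with `delta.AICc = 0` is selected. Ties on minimum AICc are
#' broken by smaller `k`, then smaller RM (parsimony).
#'
#' @param occ presence data.frame (`longitude`, `latitude`).
#' @param stack landscape `sdm_stack`.
#' @param bg_cells background cell indices; sampled via
#'   [sample_background()] when `NULL`.
#' @param fcs character vector of feature-class codes.
#' @param rms numeric vector of regularization multipliers.
#' @param agg checkerboard aggregation factors; when a presence group comes
#'   out empty, the fallbacks in `agg_fallbacks` are tried in order.
#' @param agg_fallbacks list of alternative aggregation pairs.
#' @param background_n background sample size when sampling.
#' @param n_knots hinge/threshold knots per layer.
#' @param seed seed for background sampling.
#' @param max_iter,tol optimizer controls passed to [fit_maxent()].
#' @param verbose print progress.
#' @return list with `results` (one row per combination: `fc`, `rm`,
#'   `auc_train`, `auc_test`, `auc_diff`, `or10`, `k`, `aicc`,
#'   `delta_aicc`), `selected` (`fc`, `rm`), `model` (full-data fit of the
#'   selected combination), `partition` (group ids and the aggregation
#'   used).
#' @export
tune_maxent <- function(occ, stack, bg_cells = NULL,
                        fcs = c("L", "LQ", "H", "LQH", "LQP", "LQHP", "LQHPT"),
                        rms = seq(0.5, 4, by = 0.5),
                        agg = c(10, 2),
                        agg_fallbacks = list(c(5, 2), c(4, 2), c(3, 2), c(2, 2), c(1, 2)),
                        background_n = 10000, n_knots = 50, seed = 1,
                        max_iter = 5000, tol = 1e-5, verbose = FALSE) {
  stopifnot(length(fcs) >= 1, length(rms) >= 1)
  pres_cells <- lonlat_cell(stack$layers[[1]], occ$longitude, occ$latitude)
  vc <- valid_cells(stack)
  ok <- !is.na(pres_cells) & pres_cells %in% vc
  if (!all(ok)) {
    warning(sum(!ok), " presence record(s) off-grid or masked; dropped")
    occ <- occ[ok, , drop = FALSE]
    pres_cells <- pres_cells[ok]
  }
  if (is.null(bg_cells))
    bg_cells <- sample_background(stack, background_n, seed = seed)

  part <- NULL
  for (a in c(list(agg), agg_fallbacks)) {
    g <- checkerboard2(occ$longitude, occ$latitude, stack, a)
    if (length(unique(g)) == 4L) { part <- list(groups = g, agg = a); break }
  }
  if (is.null(part))
    stop("no valid checkerboard-2 partition: some presence group is empty for every aggregation tried")
  bg_ll <- cell_lonlat(stack$layers[[1]], bg_cells)
  bg_groups <- checkerboard2(bg_ll$lon, bg_ll$lat, stack, part$agg)

  pres_X <- stack_values(stack, pres_cells)
  bg_X <- stack_values(stack, bg_cells)

  grid <- expand.grid(fc = fcs, rm = rms, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fc <- grid$fc[i]; rm <- grid$rm[i]
    fold <- lapply(1:4, function(g) {
      tr_p <- pres_X[part$groups != g, , drop = FALSE]
      te_p <- pres_X[part$groups == g, , drop = FALSE]
      tr_b <- bg_X[bg_groups != g, , drop = FALSE]
      te_b <- bg_X[bg_groups == g, , drop = FALSE]
      m <- fit_maxent(tr_p, tr_b, fc = fc, rm = rm, n_knots = n_knots,
                      max_iter = max_iter, tol = tol)
      ptr_p <- predict(m, tr_p); pte_p <- predict(m, te_p)
      ptr_b <- predict(m, tr_b); pte_b <- predict(m, te_b)
      c(auc_train = rank_auc(ptr_p, ptr_b),
        auc_test = rank_auc(pte_p, pte_b),
        or10 = if (nrow(tr_p) >= 10) or10(ptr_p, pte_p) else NA_real_)
    })
    fm <- do.call(rbind, fold)
    full <- fit_maxent(pres_X, bg_X, fc = fc, rm = rm, n_knots = n_knots,
                       max_iter = max_iter, tol = tol)
    rows[[i]] <- data.frame(
      fc = fc, rm = rm,
      auc_train = mean(fm[, "auc_train"]), auc_test = mean(fm[, "auc_test"]),
      auc_diff = mean(fm[, "auc_train"] - fm[, "auc_test"]),
      or10 = mean(fm[, "or10"]),
      k = sum(full$beta != 0),
      aicc = aicc_maxent(full, stack, pres_cells),
      stringsAsFactors = FALSE)
    if (verbose) message(sprintf("tuned fc=%s rm=%g: aicc=%.2f", fc, rm, rows[[i]]$aicc))
  }
  results <- do.call(rbind, rows)
  if (all(is.na(results$aicc)))
    stop("AICc undefined for every combination (k >= n - 1 throughout); ",
         "reduce feature complexity or add presences")
  results$delta_aicc <- results$aicc - min(results$aicc, na.rm = TRUE)
  cand <- which(!is.na(results$delta_aicc) & results$delta_aicc == 0)
  cand <- cand[order(results$k[cand], results$rm[cand])]
  sel <- cand[1]
  model <- fit_maxent(pres_X, bg_X, fc = results$fc[sel], rm = results$rm[sel],
                      n_knots = n_knots, max_iter = max_iter, tol = tol)
  list(results = results,
       selected = list(fc = results$fc[sel], rm = results$rm[sel]),
       model = model,
       partition = list(groups = part$groups, bg_groups = bg_groups, agg = part$agg,
                        pres_cells = pres_cells, bg_cells = bg_cells))
}
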