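#' Pairwise Pearson correlation of stack layers
#'
#' Correlations are computed over the jointly valid landscape cells
#' (optionally subsampled with a seed), the stabler choice when the sample
#' for screening is not otherwise specified. A zero-variance layer yields an
#' undefined (NA) row/column, which screening treats as |r| = 0, with a
#' warning.
#'
#' @param stack an `sdm_stack`.
#' @param cells optional integer cell indices over which to correlate;
#'   default all jointly valid cells.
#' @param max_cells subsample size cap when `cells` is not given.
#' @param seed seed for the subsample.
#' @return symmetric correlation matrix with layer names.
#' @export
pearson_matrix <- function(stack, cells = NULL, max_cells = 10000, seed = 1) {
  if (is.null(cells)) {
    cells <- valid_cells(stack)
    if (length(cells) > max_cells) {
      set.seed(seed)
      cells <- sort(sample(cells, max_cells))
    }
  }
  if (length(cells) < 3) stop("need at least 3 valid cells to correlate")
  X <- stack_values(stack, cells)
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    warning("zero-variance layer(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
            " (correlations undefined, treated as 0 in screening)")
  suppressWarnings(cor(X))
}

#' Collinearity screening with contribution-aware exclusion
#'
#' Repeatedly finds the surviving pair with the largest |r| at or above the
#' threshold and drops the member with the lower contribution, until all
#' kept pairs satisfy |r| < threshold. Ties between pairs are broken by the
#' canonical order of `rownames(corr)` (first offending pair in column-major
#' order); equal contributions drop the later name in that order. An
#' optional `priority` character vector (most important first) encodes
#' domain knowledge and overrides the contribution comparison: a listed
#' variable always survives against an unlisted one, and between two listed
#' variables the earlier-listed wins.
#'
#' @param corr symmetric Pearson matrix (NA entries treated as 0).
#' @param contribution named numeric vector of percent contributions, one
#'   per variable in `corr`.
#' @param threshold |r| at or above which a pair is considered collinear.
#' @param priority optional character vector of variable names, most
#'   important first.
#' @return list with `kept`, `dropped` (character vectors) and `steps`
#'   (data.frame log of each exclusion).
#' @export
screen_variables <- function(corr, contribution, threshold = 0.8, priority = NULL) {
  nms <- rownames(corr)
  stopifnot(!is.null(nms), all(nms %in% names(contribution)))
  r <- abs(corr)
  r[is.na(r)] <- 0
  diag(r) <- 0
  alive <- nms
  steps <- list()
  prefer <- function(a, b) {
    # TRUE if a should be kept over b
    pa <- match(a, priority); pb <- match(b, priority)
    if (!is.na(pa) || !is.na(pb)) {
      if (is.na(pb)) return(TRUE)
      if (is.na(pa)) return(FALSE)
      return(pa < pb)
    }
    ca <- contribution[[a]]; cb <- contribution[[b]]
    if (ca != cb) return(ca > cb)
    match(a, nms) < match(b, nms)  # tie: drop the later name in canonical order
  }
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    if (max(sub) < threshold) break
    hit <- which(sub == max(sub), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    a <- alive[hit[1, 1]]; b <- alive[hit[1, 2]]
    drop <- if (prefer(a, b)) b else a
    steps[[length(steps) + 1]] <- data.frame(
      var_a = a, var_b = b, abs_r = max(sub), dropped = drop, stringsAsFactors = FALSE)
    alive <- setdiff(alive, drop)
  }
  list(kept = alive, dropped = setdiff(nms, alive),
       steps = if (length(steps)) do.call(rbind, steps)
               else data.frame(var_a = character(), var_b = character(),
                               abs_r = numeric(), dropped = character()))
}
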