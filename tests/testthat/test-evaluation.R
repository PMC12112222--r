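test_that("rank AUC handles separation, ties and partial concordance", {
  expect_equal(rank_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(rank_auc(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(rank_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  # invariant under strictly increasing transforms
  set.seed(8)
  p <- runif(40); b <- runif(60)
  expect_equal(rank_auc(p, b), rank_auc(qlogis(p), qlogis(b)))
  expect_equal(rank_auc(p, b), rank_auc(p^3, b^3))
  # agrees with the Wilcoxon statistic
  w <- wilcox.test(p, b, exact = FALSE)$statistic
  expect_equal(rank_auc(p, b), unname(w) / (length(p) * length(b)))
})

test_that("TSS follows the 2x2 confusion table", {
  expect_equal(tss(c(0.9, 0.3), c(0.8, 0.1), 0.5), 0.0)  # sens 0.5 + spec 0.5 - 1
  expect_equal(tss(c(0.9, 0.8), c(0.1, 0.2), 0.5), 1)
  set.seed(9)
  x <- runif(2000)
  expect_lt(abs(tss(x, sample(x), 0.5)), 0.1)
})

test_that("AUC bands use the left-closed published scale", {
  expect_equal(auc_band(c(0.3, 0.5, 0.69, 0.7, 0.8, 0.9, 1.0)),
               c("fail", "poor", "poor", "fair", "good", "excellent", "excellent"))
})

test_that("jackknife gains behave under redundancy, noise, and nesting", {
  set.seed(10)
  n_bg <- 600; n_p <- 60
  sig <- runif(n_bg)
  bg <- cbind(sig = sig, dup = sig + rnorm(n_bg, sd = 1e-3), noise = runif(n_bg))
  pidx <- sample(n_bg, n_p, prob = plogis(6 * (sig - 0.5)))
  pr <- bg[pidx, ]
  jk <- jackknife_importance(pr, bg, fc = "LQ", rm = 1)
  full <- attr(jk, "gain_full")
  # dropping either member of a duplicated pair barely costs gain
  expect_equal(jk$gain_without[jk$variable == "sig"], full, tolerance = 0.05)
  expect_equal(jk$gain_without[jk$variable == "dup"], full, tolerance = 0.05)
  # a pure-noise variable carries almost no gain alone
  expect_lt(jk$rtg_alone[jk$variable == "noise"], 0.05)
  # nested feature sets: no single variable outperforms the full model
  expect_true(all(jk$rtg_alone <= full + 1e-6))
})

test_that("percent contribution normalizes path credit per variable", {
  m1 <- fit_maxent(tiny_pres_X[, 1, drop = FALSE], tiny_bg_X[, 1, drop = FALSE],
                   fc = "LQ", rm = 1)
  pc1 <- percent_contribution(m1)
  expect_equal(unname(pc1), 100)

  m <- fit_maxent(tiny_pres_X, tiny_bg_X, fc = "LQH", rm = 1, n_knots = 8)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 1e-6)
  expect_true(all(pc >= 0))
})

test_that("two equally informative variables split contribution near-evenly", {
  # swap-symmetric simulation: the two variables are exchangeable by
  # construction, so an unbiased path-credit rule must split 50/50
  res <- sapply(1:4, function(s) {
    set.seed(s)
    n <- 800
    x <- runif(n); y <- runif(n)
    bg <- rbind(cbind(u = x, v = y), cbind(u = y, v = x))
    pick <- sample(n, 150, prob = plogis(3 * (x - 0.5) + 3 * (y - 0.5)))
    pr <- rbind(cbind(u = x[pick], v = y[pick]), cbind(u = y[pick], v = x[pick]))
    m <- fit_maxent(pr, bg, fc = "L", rm = 1)
    percent_contribution(m)
  })
  expect_true(all(abs(res["u", ] - 50) < 5))
})

test_that("permutation importance isolates the informative variable", {
  set.seed(12)
  n_bg <- 800
  bg <- cbind(sig = runif(n_bg), noise = runif(n_bg))
  pidx <- sample(n_bg, 120, prob = plogis(8 * (bg[, "sig"] - 0.5)))
  m <- fit_maxent(bg[pidx, ], bg, fc = "LQ", rm = 1)
  pi1 <- permutation_importance(m, bg[pidx, ], bg, seed = 1, n_rep = 10)
  expect_equal(sum(pi1), 100, tolerance = 1e-6)
  expect_gt(pi1[["sig"]], 95)
  expect_lt(pi1[["noise"]], 5)
  # averaging over 10 repeats stabilizes across permutation seeds
  pi2 <- permutation_importance(m, bg[pidx, ], bg, seed = 2, n_rep = 10)
  expect_lt(max(abs(pi1 - pi2)), 2)  # within +/- 2 percentage points
})

test_that("response curves recover monotonicity and interior optima", {
  set.seed(13)
  n_bg <- 800
  bg <- cbind(x = runif(n_bg), z = runif(n_bg))
  # monotone truth in x
  pidx <- sample(n_bg, 150, prob = plogis(6 * (bg[, "x"] - 0.5)))
  m <- fit_maxent(bg[pidx, ], bg, fc = "L", rm = 1)
  rc <- response_curve(m, "x", n = 51)
  expect_true(all(diff(rc$logistic) >= -1e-9))
  expect_true(all(rc$logistic >= 0 & rc$logistic <= 1))

  # interior optimum at x = 0.6
  pidx2 <- sample(n_bg, 200, prob = exp(-30 * (bg[, "x"] - 0.6)^2))
  m2 <- fit_maxent(bg[pidx2, ], bg, fc = "LQ", rm = 1)
  rc2 <- response_curve(m2, "x", n = 101)
  step <- diff(rc2$value[1:2])
  expect_lt(abs(attr(rc2, "argmax") - 0.6), 5 * step)

  # crossing finder: linear interpolation on a known line
  cr <- curve_crossings(data.frame(value = 0:2, logistic = c(0, 0.5, 1)), 0.25)
  expect_equal(cr, 0.5)
})
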