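---
title: "maxsdm: methods, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maxsdm: methods, defaults and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(maxsdm)
```

## The modelling problem

`maxsdm` estimates where a taxon can live from presence-only records and a
stack of co-registered environmental rasters (bioclimatic summaries,
topography, vegetation indices), then tracks how that suitable range moves
between climate periods. The statistical core is the maximum-entropy
density estimate over landscape cells: among all distributions whose
feature expectations match the presence sample, take the one closest to
uniform. Equivalently, fit the Gibbs family
$P(x) \propto e^{\beta \cdot f(x)}$ over a background sample by minimizing

$$\mathcal{L}(\beta) \;=\; -\frac{1}{m}\sum_{i \in \text{presence}} \eta(x_i)
\;+\; \log \bar Z(\beta) \;+\; \sum_j \lambda_j |\beta_j|,$$

with $\eta = \beta \cdot f(x)$ and $\bar Z$ the background mean of
$e^{\eta}$. $\mathcal{L}$ is convex, $\mathcal{L}(0) = 0$, and the
regularized training gain reported everywhere in the package is
$-\mathcal{L}$ at the optimum — the log-likelihood improvement over the
uniform null, which is therefore always non-negative.

Assumptions worth stating plainly: occurrences are an unbiased (after
thinning) sample of the realized niche; the background characterizes the
available environment; suitability is a function of the supplied layers
only (no dispersal limits, no biotic interactions); and projection to other
climates is meaningful only up to the clamped training range of each layer.

## Features and regularization

Feature classes follow the classic maxent taxonomy:

* **L** — one feature per layer; **Q** — its square; **P** — all pairwise
  products;
* **H** — forward hinges $\max(0, x-k)/(x_{\max}-k)$ and reverse hinges
  $\max(0, k-x)/(k-x_{\min})$ at `n_knots` interior background quantiles
  (default 50 per layer);
* **T** — step indicators $x > k$ at the same knots.

All features are scaled to $[0,1]$ on the background (L/Q/P min–max;
hinge/threshold by construction), so penalties are comparable across
classes. The per-feature penalty is
$\lambda_j = \mathrm{RM} \cdot \beta_0(\text{class}, m) \cdot
\max(s_j, 10^{-3})/\sqrt{m}$, where $\beta_0$ interpolates the published
default tables against the presence count $m$ (hinge constant at 0.5;
linear, quadratic, product and threshold tables decreasing in $m$), $s_j$
is the presence-sample SD of the scaled feature, and the $10^{-3}$ floor
keeps near-constant features from becoming penalty-free. Doubling RM
doubles every $\lambda_j$ exactly.

## The optimizer

Cyclic coordinate descent on the penalized objective, in compiled code.
Each coordinate step minimizes the local quadratic model of the smooth part
plus the exact L1 term (a soft-threshold update), with step halving to
guarantee monotone descent of the true objective and a per-update step cap
of 0.5. The cap serves two purposes: it bounds the `exp` arguments, and it
keeps updates in the small-step regime in which objective credit accrues
alternately across competing features, which is what makes the path-based
percent-contribution accounting meaningful (a swap-symmetric two-variable
simulation splits 50/50 within ±2 points). After each full sweep the
optimizer iterates over the active (nonzero) set until stable — the same
schedule that makes lasso solvers fast on wide hinge expansions. Defaults:
`tol = 1e-5` on the per-sweep objective decrease, `max_iter = 5000` sweeps,
matching the convergence budget conventional for this model family. Fits
with up to a few features agree with independent golden-section and
Nelder–Mead minimizations of the same objective to $10^{-4}$ or better
(this is a test invariant, not an aspiration).

Degenerate inputs are refused with diagnostics: fewer than 5 presences,
all-constant features, non-positive RM. Constant features are silently
dropped at feature-construction time (they carry no information and would
make scaling ill-defined).

## Thinning, screening, tuning

**Thinning.** Records are visited in a seed-shuffled order and kept iff at
least `min_km` (default 2.5 km) from every kept record — a maximal
independent set for that order, so output pairwise distances are provably
$\ge$ `min_km` and the operation is idempotent. The seeded shuffle avoids
biasing retention toward file order in dense clusters. Whether one should
thin at 2.5 km or one-per-cell at the raster resolution (a 2.5 arc-min
cell is ~4.6 km on the ground) is genuinely ambiguous in common protocol
descriptions; both are available through `min_km`, and 2.5 km is the
default.

**Screening.** Pearson correlations are computed over all jointly valid
landscape cells (subsampled with a seed above 10,000 cells) rather than at
presence points only — the landscape-wide matrix is the stabler choice and
the protocol this mirrors does not specify otherwise. Exclusion is
iterative: take the surviving pair with the largest $|r| \ge 0.8$, drop the
lower-contribution member (contributions from a default-settings baseline
fit), repeat. "Biological significance" is operationalized as an optional
user-supplied priority list that overrides the contribution comparison.
Ties break by the canonical layer order, making the kept set deterministic.

**Tuning.** The default grid crosses seven feature classes
(`L, LQ, H, LQH, LQP, LQHP, LQHPT`) with eight multipliers (0.5–4.0 by
0.5) — 56 candidates. Occurrences and background are partitioned by the
hierarchical checkerboard-2 scheme: a fine board (block edge `agg[1]`
cells) and a coarse board (edge `agg[1]*agg[2]`) each contribute one parity
bit; the two bits give four spatially structured folds. Default aggregation
(10, 2), with an automatic fallback ladder when a presence fold comes out
empty. Per candidate we report fold-averaged training/testing AUC, their
difference (overfitting diagnostic), and the 10th-percentile omission rate
(ceiling-index threshold convention); the full-data refit supplies the
nonzero-coefficient count $k$ and AICc with the likelihood standardized
over all valid landscape cells (the Warren–Seifert convention, rather than
background-sample standardization — a documented switch). Selection is
`delta.AICc = 0`; exact ties prefer smaller $k$, then smaller RM
(parsimony). AICc is undefined when $k \ge n-1$; if that happens for the
whole grid the tuner aborts with a diagnostic rather than guessing.

## Thresholding, grading, change accounting

The MTSPS threshold maximizes test sensitivity plus specificity over the
candidate set of observed prediction values, background points serving as
pseudo-absences; ties take the smallest threshold. Grades are multiples of
the threshold, $(t, 2t, 3t)$ capped at 1 — the conventional
0.22/0.44/0.66 grading is the $t = 0.22$ case — with boundary values
belonging to the higher class. Binarization for change analysis uses strict
exceedance (`HSI > t`); the boundary case `HSI = t` is assigned
non-suitable, since the two strict inequalities in the usual protocol
leave equality unassigned and "suitable" should mean exceeding the
threshold.

Change maps code absent/absent as 0, expansion as −1, stable as 1,
contraction as 2. Areas are sums of spherical cell areas
$(c \cdot 111.19493\ \mathrm{km})^2 \cos\varphi$ at each cell's center
latitude (mean Earth radius 6371.0088 km; no ellipsoid — the precision of
the quantities reported at $10^4\ \mathrm{km}^2$ scale does not demand
one), so `area_future = area_current + gain − loss` holds exactly by
construction. Centroids are area-weighted means of suitable-cell centers;
shifts report haversine distance, initial great-circle bearing, an
8-sector compass label, and speed = distance/years with consecutive
scenario decades ("2050s" → "2070s") spanning 20 years. No dispersal
constraint is applied between periods (unrestricted-migration assumption).

## The synthetic study landscape

`make_scenario()` is the package's reference fixture: a 120×120-cell,
2.5 arc-min grid (≈5° × 5° in subtropical East Asia), five layers built
from Gaussian random fields with autocorrelation length 8 cells, a mixing
matrix inducing moderate collinearity on two layer pairs (|r| ≈ 0.6–0.7,
below the screening threshold), a latitudinal gradient of −0.5 SD per
degree on the temperature-like layer `bio1`, and the truth
$\mathrm{logit}^{-1}(0.25 + 1.4\,\mathrm{bio1} - 0.8\,\mathrm{bio2}^2)$.
200 presences are drawn truth-proportionally without replacement; the
future stack adds +0.75 SD to `bio1`, which translates the suitable band
poleward by 1.5°. These sizes were chosen once as a realistic desk-scale
analogue of a regional 2.5 arc-min study — large enough for spatial
partitioning and recovery tests (the fitted logistic surface correlates
with the truth at $r > 0.9$), small enough to run everywhere.

What the generator deliberately does *not* emulate: GCM physics, scenario
downscaling, interannual variability, sampling bias (available as an
optional bias field, off by default), and non-climatic constraints. Passing
recovery tests on this landscape therefore demonstrates correctness of the
estimation and accounting machinery, not predictive skill on real
distributions.

## Problem sizes in tests and the acceptance script

Unit and property tests run on a 40×40-cell, 3-layer, 80-presence
landscape with a few hundred background points and reduced knot counts —
sizes chosen so the full suite completes in about a minute while still
exercising every code path. The acceptance computation runs the full
56-combination grid on the default 120×120 scenario with 5,000 background
points and 10 hinge knots per layer, then fits, grades and projects the
selected model at the full background size; grid cardinality, AICc
selection and all conservation identities are invariant to those two
reductions.

## Known limitations

* Path-based percent contribution is order-dependent by nature (as in all
  sequential maxent implementations); permutation importance is the
  stabler measure and both are reported.
* AICc on presence-only likelihoods is a model-ranking heuristic, not an
  absolute fit measure; it is used only to rank the 56 candidates.
* The logistic output's prevalence-0.5 convention is inherited from the
  classic formulation; cloglog output is not implemented.
* `bearing_deg` is the spherical initial azimuth; over hundreds of km the
  8-sector compass label is robust, but the azimuth itself ignores
  ellipsoidal corrections (~0.1°).
* Reprojection is out of scope: all inputs must already share a geographic
  WGS84 grid.
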