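---
title: "Delineating livestock ecotypes with presence-background niche models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating livestock ecotypes with presence-background niche models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Indigenous livestock populations that have adapted to distinct habitats are
candidate *ecotypes*: management units for conservation and breeding. Where
phenotypic and genomic data are not yet available, the habitats themselves
can be characterized. This package implements that protocol for
village-sampled populations: environmental raster layers and village
coordinates go in; a clustering of populations into candidate ecotypes,
with the full supporting evidence (variable screening, model tuning,
accuracy statistics, pairwise niche similarity), comes out.

The modelling unit is the *district* (an administrative population of
villages). Each village contributes its GPS point plus nine random points
inside a square of area 1.2 km² centred on it, so a district with two or
three villages yields 20 or 30 presence points. Presences are compared
against the whole study landscape (the *background*), not against absences,
which are unobservable for free-ranging village livestock.

## The maximum-entropy niche model

For each population we fit a Gibbs distribution over the valid background
cells $x$,

$$ \mathrm{raw}(x) = \frac{e^{\lambda \cdot f(x)}}{Z(\lambda)}, $$

where $f(x)$ are feature transforms of the environmental covariates and
$\lambda$ minimizes the L1-regularized objective

$$ f(\lambda) = -\frac{1}{m}\sum_{i\in\text{presence}} \lambda\cdot f(x_i)
   + \log \sum_{x\in B} e^{\lambda\cdot f(x)}
   + \sum_j \beta_j |\lambda_j| . $$

This is the classical presence-background maximum-entropy estimator: the
minimizer matches the model's feature expectations to the presence sample
means within the box constraints $\pm\beta_j$ (the KKT conditions, which
the test suite audits directly).

**Feature classes.** Continuous covariates are min-max scaled to $[0,1]$ on
the background; the classes are linear (L), quadratic (Q), pairwise product
(P), threshold (T; step indicators) and hinge (H; forward and reverse
ramps), with knots at evenly spaced interior quantiles of the background
distribution (`n_knots`, default 30; the packaged desk scenario uses 8).
Categorical covariates always enter as one indicator per level (C).

**Regularization.** $\beta_j = \mathrm{BM}\times c_{\text{class}}(m)\times
s_j/\sqrt{m}$, with $m$ the presence count, $s_j$ the presence-sample
standard deviation of feature $j$ (floored at 0.001 on the $[0,1]$ feature
scale so degenerate features stay bounded), and $c_{\text{class}}(m)$ the
published per-class default constants, interpolated piecewise-linearly in
$m$ and exposed in `reg_constant()`. The beta multiplier BM scales all
bounds at once.

**Optimizer.** Cyclic coordinate descent with soft-thresholding: each
coordinate takes a Newton step on the smooth part, soft-thresholded at
$\beta_j$, with step halving so the objective never increases (asserted
every sweep in the tests). Convergence is declared when a full sweep
improves the objective by less than `tol` ($10^{-7}$), with a cap of 500
sweeps. On toy instances the fitted objective agrees with an independent
box-constrained quasi-Newton solver to $10^{-6}$. Every accepted update's
objective decrease is recorded; these path credits are what percent
contribution attributes to variables, following the convention that
contribution is a property of the training path rather than a drop-one
statistic.

**Outputs.** `raw` is renormalized to sum to one over the projection grid;
`logistic` is $\mathrm{raw}\,e^H/(1+\mathrm{raw}\,e^H)$ with $H$ the
entropy of the fitted training distribution (so a null model scores 0.5
everywhere); `cumulative` at a cell is 100 times the raw mass of cells
scoring at or below it. The three surfaces are rank-consistent by
construction. Projection values outside the training bounds are clamped
into the scaled range and counted.

## Model selection and evaluation

Candidate models are the Cartesian product of feature-class sets and beta
multipliers (`enumerate_grid()`; the packaged default grid is all 15
non-empty subsets of {L, Q, H, T} plus {L, Q, P, H, T}, crossed with BM
1–12 — 192 candidates). Each candidate is scored by
$\mathrm{AICc} = 2K - 2\ell + 2K(K+1)/(n-K-1)$ with $K$ the count of
non-zero coefficients and $\ell$ the presence log-likelihood under the
grid-normalized raw distribution; candidates with $n-K-1\le 0$ are flagged
invalid and never selected. Ties break toward fewer parameters, then
smaller BM, then grid order, making selection order-invariant.

Occurrences are split 75/25 into training and test; the training part is
additionally cut into ten spatially structured ("regionalised") folds by
sorting on longitude and slicing into contiguous blocks — a declared
convention, since contiguous-block folds are the simplest spatial
cross-validation respecting the east-west environmental gradients of the
study region.

Accuracy is the rank-based AUC (Mann–Whitney probability that a presence
outscores a background cell, ties counted one half — invariant to the
monotone transforms between the three output scales). Variable importance
is assessed three ways: jackknife refits (each variable alone / excluded,
training and test gain and AUC), percent contribution from the fitting
trace (product features split credit evenly), and permutation importance
(drop in training AUC after jointly permuting a variable across presence
and background rows, floored at zero, normalized to 100%).

## Variable screening

Screening runs three passes. (1) Spearman rank correlations over the
background cells, annotated with the conventional strength bands and
Shapiro–Wilk normality statistics (diagnostic only — rank correlation is
used regardless); greedy pruning visits variables in expert priority order
and keeps a variable iff it is below the threshold (default 0.6) against
everything already kept. (2) PCA on standardized covariates for visual
inspection of redundancy. (3) The decisive pass is an iterative
maxent-based selection: per beta multiplier, fit on the current set, drop
variables contributing less than the threshold (default 5%), then drop the
lower-contribution member of each background-correlated pair at or above
the threshold, and repeat to stability; the stable model with the smallest
AICc defines the selected set. Correlations are computed on background
cells rather than occurrence rows because collinearity is a property of
the covariate space the model normalizes over.

## Pairwise niche similarity and clustering

Fitted populations are compared pairwise on a common grid: Pearson
correlation of the logistic surfaces, and distribution overlap of
renormalized surfaces — Hellinger-based $I = 1-\tfrac12\sum(\sqrt{p}-
\sqrt{q})^2$ and Schoener's $D = 1-\tfrac12\sum|p-q|$ (both in $[0,1]$,
equal to one iff the distributions coincide, and satisfying $I \ge D$).

*Which surface to overlap* is genuinely open. We compute $I$ on the
renormalized **logistic** surfaces: the raw Gibbs surface of a
high-accuracy model concentrates nearly all mass on a handful of cells, so
raw-surface overlap between two populations of the same ecotype is
dominated by sampling noise in those few cells; the logistic transform
compares the same information on a bounded, better-conditioned scale, and
matches the common practice of overlapping the mapped outputs as
delivered. The `overlap_surface` configuration entry restores raw-surface
overlap if wanted.

Populations are then clustered on the Euclidean distances **between
similarity-matrix rows** (each population is represented by its profile of
similarities to everyone, as the protocol prescribes) under four linkages
— single, complete, average and Ward, the latter in the
squared-distance/Lance–Williams convention with heights reported on the
distance scale. The linkage with the largest agglomerative coefficient
$AC = \mathrm{mean}_i\,(1 - m_i/m_{\text{final}})$ (first-merge over last-
merge height) is chosen, with ties resolved toward Ward. The group count
$k$ maximizes the mean silhouette width over a configurable range, but the
final count is a judgement the configuration can pin (`k_override`); the
packaged scenario pins $k=4$, mirroring a protocol whose final grouping
combined the dendrograms with jackknife and contribution evidence rather
than an automatic rule. Populations whose co-membership pattern differs
between the two metrics are flagged in the run report.

## The synthetic landscape generator

The generator exists so the whole protocol is runnable and falsifiable
offline. It emulates: a ~1 km study grid (64×64 cells by default); seven
continuous layers with a realistic cross-correlation structure (three
"climatic" drivers, four distractors correlated 0.6–0.85 with them, the
collinearity typical of bioclimatic stacks) built by Gaussian-blurring
independent white-noise fields and mixing them through the Cholesky factor
of the target correlation matrix; one categorical layer (two levels,
finer-grained patches, as crop dominance varies at field scale); four
planted ecotypes as Gaussian niches over the drivers; and the village
design — four districts per ecotype, two villages per district, village
centres drawn with probability proportional to true suitability, altitudes
drawn from ecotype-specific bands, ten occurrence points per village (320
in total).

Calibration choices, made once: spatial smoothness `blur_sigma = 1.5`
cells, so that a 1.2 km² village square straddles cells with measurably
different covariate values (much smoother landscapes make each village a
single covariate point and the district models degenerate); optima at
±1.2 background standard deviations with niche width 0.5 sd, i.e.
differing drivers are 4.8 widths apart — comfortably inside the
"well-separated" regime the recovery property assumes. The packaged
scenario tunes over {L, LQ, LQP} × BM {1, 2, 4}: the planted response is
log-quadratic, and with ~2 distinct covariate cells per district the
hinge/threshold classes (available, and unit-tested) overfit district
models; the full 192-candidate grid remains the package default for real
data.

What the generator does **not** emulate: geostatistical structure beyond
Gaussian smoothing (no variograms, anisotropy or terrain), measurement
error in layers or GPS points, road/accessibility sampling bias, and any
ecological process beyond a static Gaussian niche. Passing the recovery
tests therefore shows the pipeline is internally coherent — it finds
structure that is genuinely there, under its own model family — not that
real landscapes satisfy these assumptions.

## Numerical conventions and degenerate inputs

Normalizers use log-sum-exp throughout; raster cells are half-open with
the origin at the upper-left, so edge points belong to exactly one cell;
categorical layers are always resampled nearest-neighbour; constant
variables are flagged (screening) or produce a constant 0.5 feature
(model); maps with fewer than 10 jointly valid cells refuse to be
compared; per-district and per-village random streams derive from stable
label hashes of the global seed, so adding a district never perturbs
another's points. Reports serialize with full precision and no
timestamps, making byte-identical reproduction a testable property.

## Known limitations

Rasters must share a CRS (WGS84 geographic is assumed; no reprojection);
supported formats are ESRI ASCII grid (read/write) and single-band TIFF
with a world-file sidecar (read). The background is never subsampled — at
desk scale this is exact and keeps per-population maps directly
comparable, but it is quadratic-memory-unfriendly for continental grids.
Percent contribution inherits the path-dependence of the training
algorithm; the silhouette rule for $k$ is a heuristic and is deliberately
overridable. District models fitted on two villages are close to the
small-sample limit of the method; the real protocol's robustness at that
limit is inherited, not improved upon.
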