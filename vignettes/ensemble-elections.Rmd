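---
title: "Election ensembles for presence-background distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Election ensembles for presence-background distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Occurrence records tell us where a species was seen, never where it is
absent. Presence-background species distribution models (SDMs) handle this
by contrasting recorded presences against *background* points placed at
random across the study region, and fitting a scorer that ranks each raster
cell by habitat suitability. `sdmelect` implements a complete pipeline of
this kind, organised around three ideas:

1. **Algorithmic pluralism.** Rather than selecting one "best" model, five
   algorithm families — a feed-forward neural network (ANN), gradient
   boosted trees (GBM), an L1-penalized maximum-entropy-style logistic
   regression (MaxEnt), random forest (RF) and a support vector machine
   (SVM) — are each fitted under k-fold cross-validation, giving a pool of
   `n_algorithms * k` fitted models per training configuration.
2. **Election ensembles.** Each fitted model's continuous suitability map is
   binarized at its own threshold, and binary maps are then combined by
   per-cell *voting*: a majority vote (MV; quorum `ceiling((m+1)/2)`, i.e.
   3 of 5 fold maps or 13 of 25 pooled models), a unanimous decision (UD),
   and a mean ensemble that averages the fold surfaces and thresholds.
3. **Range-mask validation.** Binary predictions are scored by confusion
   matrix against an *estimated range*: the union of fixed-radius circular
   buffers around the occurrences, rasterized onto the analysis grid.

With the default protocol — two training configurations (all occurrences,
and only those inside a sub-region polygon), five algorithms, five folds,
three per-algorithm ensembles and two collective elections — the pipeline
evaluates `2 * (5*5 + 5*3 + 2) = 84` classification maps.

## The model, step by step

### Covariates

All covariate layers share one grid and are min–max normalized to $[0,1]$
per layer, so every covariate enters the learners with equal weight:

$$z = \frac{x - \min x}{\max x - \min x}.$$

Normalization statistics are computed once over the full analysis extent
and shared by training and prediction; constant layers are set to all-0
with a warning rather than aborting a run. From an elevation layer,
`terrain_metrics()` derives slope and aspect by Horn's 8-neighbour
finite-difference method and the Terrain Ruggedness Index (TRI) as the mean
absolute elevation difference between a cell and its 8 neighbours. Aspect
is a circular quantity but is normalized linearly like every other layer —
a deliberate replication of common practice that discards the topology at
0/360°; flat cells report aspect 0.

### Cross-validation and thresholding

Presences are split into `k` seeded folds whose sizes differ by at most
one. The background set is attached *in full* to both the fitting and the
evaluation side of every fold: backgrounds are never held out. This choice
maximizes the environmental contrast available to each fold but makes fold
AUC optimistic for flexible learners, which partially memorize background
feature vectors seen in training. Users comparing algorithms should keep in
mind that this optimism is not uniform across families.

Each fold's continuous map is converted to a binary one at the threshold
maximizing sensitivity + specificity (Youden's criterion) over the observed
evaluation scores — held-out presences vs the full background — under the
rule *suitable iff score ≥ t*, ties broken toward the smallest candidate.

### Elections and the unanimity question

Votes are counted per cell. The majority vote needs `quorum` suitable
votes. For the unanimous decision two semantics exist and genuinely differ:

* **Exclusion (default):** cells where members disagree are marked
  `no_consensus` and excluded from confusion statistics. The UD map is then
  scored only on cells it is certain about, which is why a UD ensemble can
  report *higher* sensitivity than the majority vote it is logically nested
  inside.
* **Forced binary** (`ud_forced_binary = TRUE`): contested cells are
  classed unsuitable. This restores the strict nesting UD-suitable ⊆
  MV-suitable, with its deterministic consequences (UD sensitivity ≤ MV
  sensitivity, UD specificity ≥ MV specificity).

With many diverse members the exclusion-style UD can abstain on *every*
cell; `run_experiment()` records `NA` statistics for such a map rather than
failing the run.

### Range estimation

`buffer_range_mask()` marks a cell in-range iff the distance from its
centre to the nearest occurrence is at most the buffer radius — planar
Euclidean on kilometre grids, haversine (Earth radius 6,371 km) on
geographic ones. This is exactly the merged-buffer polygon rasterized at
cell-centre precision, without any vector-polygon machinery. The function's
default radius (49 km) reflects field-reported post-release movement
distances for upland game birds at continental scale; for the 100-km
synthetic landscape below the package's standard study uses 5 km, keeping
roughly the same ratio of dispersal distance to domain extent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 5 | cross-validation folds |
| `n_background` | 10,000 | background points when none are supplied |
| `radius_km` | 49 | dispersal-buffer radius (km) |
| `fold_quorum` | `ceiling((k+1)/2)` = 3 | per-algorithm majority quorum |
| `collective_quorum` | `ceiling((5k+1)/2)` = 13 | pooled-election quorum |
| `ud_forced_binary` | `FALSE` | unanimity semantics (see above) |
| ANN | size 8, decay 0.01 | single hidden layer, logistic output |
| GBM | 1,000 trees, eta 0.01, depth 3 | bernoulli loss |
| MaxEnt | L1, BIC-chosen lambda | linear + quadratic + product features |
| RF | 500 trees | default feature subsampling |
| SVM | RBF kernel, cost 1 | probability-calibrated |

No class reweighting is applied by default despite the roughly 1:8
presence:background imbalance; `weights = TRUE` in a family's
hyperparameters enables inverse-frequency weighting. Every model is seeded:
per-fold seeds are derived deterministically from the master seed and the
(training set, algorithm, fold) triple, so any single model can be refitted
bit-identically in isolation.

## The virtual-species generator

Real pipelines of this kind consume interpolated climate rasters and
citizen-science occurrence feeds. `simulate_truth_bundle()` replaces both
with a fully known synthetic system so that every stage is testable and the
truth is available for recovery checks:

* **Landscape:** per layer, seeded white noise smoothed with a Gaussian
  kernel (`smoothing_scale` cells, default 5) and min–max normalized — a
  stationary random field with the strong positive spatial autocorrelation
  interpolated climate surfaces show. An elevation field (0–2 km relief)
  feeds slope/aspect/TRI.
* **Species:** suitability is
  $\mathrm{logistic}(\beta_0 + \sum_i \beta_i z_i + \sum_i \gamma_i z_i^2)$.
  The standard scenario uses a 100×100 grid of 1-km cells with six
  covariates, two informative ($\beta = +4$ and $-4$, $\gamma = -2$) and
  four pure noise, with $\beta_0 = 0$ so the field spans both classes.
* **Samples:** 300 presence cells drawn proportional to suitability
  (points uniform within the cell), 10% exact-coordinate duplicates planted
  to exercise deduplication, and 2,000 uniform background points.
* **Truth targets:** the suitability surface itself, and a ground-truth
  range defined as suitability ≥ 0.5.

```{r, eval = FALSE}
library(sdmelect)
bundle <- simulate_truth_bundle(seed = 1)
config <- experiment_config(radius_km = 5, seed = 1)
run <- run_experiment(bundle, config)
report(run)$table
```

### What the generator does and does not emulate

It reproduces the *statistical shape* the pipeline assumes: spatially
autocorrelated covariates, presence sampling biased toward suitable cells,
coordinate duplicates, and uniform background. It does **not** emulate real
coastlines or domain masks, observation-effort bias, the covariance
structure among real bioclimatic variables, or a species with a sharply
bounded climatic niche. That last point matters for interpreting results:
min–max normalization of a smoothed Gaussian field concentrates covariate
values near mid-range, so with coefficients of magnitude 4 the true
linear predictor spans only a few units and even the *true* suitability
surface separates presences from background only moderately. Passing tests
therefore demonstrate that the machinery is correct, deterministic and
self-consistent — not that this scenario reaches the discrimination levels
reported for real, sharply differentiated niches. The package's acceptance
script prints the realized recovery statistics (fold AUC by family,
rank correlation of the pooled surface with the truth, collective-MV
accuracy against the true range) for exactly this reason.

## Numerical choices and degenerate inputs

* Cells are half-open rectangles `[x_left, x_right) × [y_bottom, y_top)`;
  a point on a shared edge belongs to exactly one cell.
* Threshold candidates are the observed scores only; ties toward the
  smallest candidate make the choice deterministic.
* AUC is the rank-based Mann–Whitney statistic with ties counted 0.5.
* Undefined confusion ratios (no positives or no negatives among evaluable
  cells) are `NA`, never 0.
* Fold statistics use the sample (n−1) standard deviation; a single value
  reports `NA`.
* Constant covariate layers normalize to all-0 with a warning.
* Polygon containment counts the boundary as inside; edge membership is
  decided by an explicit point-on-segment test ahead of ray crossing.
* Terrain edge cells use the neighbours that exist (TRI averages over the
  available ones; the Horn stencil is completed by edge replication), so a
  locally constant neighbourhood always yields slope = TRI = 0.

## Problem sizes

The test suite exercises the full dual-configuration protocol on the
standard 100×100 scenario (one run, shared across the acceptance checks)
and smaller 25–40 cell grids elsewhere; oracle-equivalence checks use up to
500 scores and 40×40 grids, where brute-force enumeration is exact and
fast. These sizes are the package's reference configuration for
reproducible examples; all of them scale up by changing the
`landscape_spec()` and `experiment_config()` arguments.

## Known limitations

* One grid: no reprojection, resampling, or multi-resolution stacks.
* The evaluation inherits the background-reuse optimism discussed above;
  no spatial-block cross-validation is offered.
* Aspect's circular topology is discarded by linear normalization.
* Thresholds come from the same fold-evaluation data as the reported fold
  statistics; no third split exists.
* Range estimation is purely geometric — no dispersal barriers, kernels or
  alpha hulls.
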