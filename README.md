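# sdmelect

Election ensembles for presence-background species distribution models.

Occurrence feeds record where a species was seen, never where it is
absent. Presence-background SDMs contrast occurrences against randomly
placed background points and rank every raster cell by suitability.
`sdmelect` implements a full pipeline of this kind built around *ensemble
elections*: five algorithm families (ANN, GBM, MaxEnt-style penalized
logistic regression, RF, SVM) are fitted under k-fold cross-validation,
each fold map is binarized at its sensitivity+specificity-optimal
(Youden) threshold

```
t* = argmax_t  [ sens(t) + spec(t) ],    suitable ⇔ score ≥ t*,
```

and binary maps are combined by per-cell voting — a majority vote (MV,
quorum ⌈(m+1)/2⌉: 3 of 5 fold maps, 13 of 25 pooled models), a unanimous
decision (UD), and a mean ensemble (average surface at the average
threshold). Every classification map is validated by confusion matrix
(accuracy, sensitivity, specificity) against an estimated range built by
merging fixed-radius dispersal buffers around the occurrences. The default
dual-configuration protocol (all occurrences + a sub-region training set,
5 algorithms × 5 folds, 3 per-algorithm ensembles, 2 collective elections)
evaluates 84 classification maps.

Because real inputs of this kind (climate rasters, vetted occurrence
downloads) are bulky and external, the package ships a virtual-species
simulator: spatially autocorrelated covariate landscapes, a known logistic
linear-quadratic suitability truth, presences drawn proportional to
suitability (with planted coordinate duplicates), and uniform background —
so the entire pipeline is testable and recovery can be measured against a
known truth. It is aimed at ecologists studying introduced or expanding
species who want a reproducible, fully seeded ensemble protocol.

## Worked example

```r
library(sdmelect)

bundle <- simulate_truth_bundle(
  landscape_spec(rows = 50, cols = 50, n_covariates = 4, seed = 0),
  n_presence = 120, n_background = 600, seed = 11)
bundle
#> <truth_bundle> 50 x 50 grid, 8 layers, 132 presence records, 600 background points (seed 11)

config <- experiment_config(algorithms = c("maxent", "rf"), k = 3, radius_km = 5,
                            hyperparameters = list(rf = list(ntree = 200)),
                            seed = 11)
run <- run_experiment(bundle, config)
run
#> <sdm_experiment> 2 training set(s) x 2 algorithms x 3 folds: 28 evaluated maps (seed 11)

report(run)$table
#> # A tibble: 16 × 6
#>    training_set algorithm  ensemble accuracy sensitivity specificity
#>  1 full         maxent     Mean        0.728       0.677       0.956
#>  2 full         maxent     MV          0.758       0.717       0.941
#>  3 full         maxent     UD          0.774       0.704       0.988
#>  4 full         rf         Mean        0.665       0.625       0.848
#>  5 full         rf         MV          0.675       0.636       0.848
#>  6 full         rf         UD          0.710       0.651       0.923
#>  7 full         collective MV          0.673       0.609       0.963
#>  8 full         collective UD          0.802       0.721       0.994
#>  9 subregion    maxent     Mean        0.314       0.169       0.969
#> ...
```

The 132 raw records contain 12 planted duplicates; `run_experiment()`
deduplicates to 120, samples folds, fits each algorithm per fold,
thresholds and binarizes each fold map, and scores everything against the
5-km buffer range mask. In the table, each row is one ensemble: e.g. the
collective UD over all 6 fold models classifies 80.2% of evaluable cells
correctly, with sensitivity 0.721 (in-range cells called suitable) and
specificity 0.994 (out-of-range cells called unsuitable) — UD rows are
scored only on cells where all members agree, which is why they can beat
the majority vote on both axes. Per-fold summaries are in
`report(run)$fold_summaries`:

```r
dplyr::filter(report(run)$fold_summaries, statistic == "auc")
#>   training_set algorithm statistic     n  mean     sd
#> 1 full         maxent    auc           3 0.679 0.0224
#> 2 full         rf        auc           3 0.778 0.0290
#> 3 subregion    maxent    auc           3 0.936 0.0105
#> 4 subregion    rf        auc           3 0.881 0.0513
```

`tidy(run)` returns every metric as a long tibble, `glance(run)` a one-row
overview, and `autoplot(run)`, `autoplot(run$range_mask)` or
`autoplot(run$maps[["full/collective/collective_ud"]])` draw the results.
See the vignette in `vignettes/ensemble-elections.Rmd` for the model,
its assumptions, and every numerical convention.

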