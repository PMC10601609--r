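# svmga

Embedded genetic-algorithm feature selection for support vector machine
classifiers on small-sample, high-dimensional binary outcome data.

## The problem

Clinical prediction problems often come as a short, wide table: the
motivating setting is the prediction of periventricular leukomalacia (PVL),
a rare neonatal brain injury after cardiac surgery, from 248 wavelet-derived
features of postoperative vital-sign recordings in 56 neonates (32
positive), with 38 samples for training and 18 held out. At `n << d` almost
any feature subset fits the training data, so selecting the few features
that actually generalize — without ever consulting the held-out set — is the
whole game.

`svmga` implements an **embedded wrapper**: a genetic algorithm searches the
space of binary feature masks, and each candidate subset of `m` of the `d`
features is scored by training a linear SVM on it and evaluating the
three-term fitness

```
FF  = FF1 + FF2 + FF3
FF1 = 1 / ACC_train             (inverse training accuracy)
FF2 = a * m / d                 (cardinality penalty)
FF3 = b / width,  width = 2 / ||w||_2   (inverse geometric margin)
```

where `w = sum_i alpha_i y_i x_i` is the SVM's dual decision-boundary vector.
The GA (roulette/rank selection, single-point crossover, bit-flip mutation,
elitism) minimizes `FF`; the margin term steers the model toward subsets
with the widest class separation, a generalization proxy that is independent
of the test data. Per-epoch test accuracy is recorded for monitoring only —
poisoning the test labels leaves the entire search trajectory bit-identical.

For comparison the package also provides the classical **filter benchmark**:
mutual-information relevance ranking, threshold selection, and
sequential-elimination accuracy sweeps over four reference classifiers
(pruned decision tree, RBF SVM with `gamma = 1/m`, cost-tuned linear SVM,
4-nearest-neighbour), plus a seeded synthetic cohort generator with planted
informative features so everything is testable without the (undeposited)
clinical data.

## Worked example

Plant 5 informative features (6 sd class separation) among 60, split 38/18,
and let the GA select:

```r
library(svmga)
cohort <- generate_cohort(cohort_config(n_features = 60, n_informative = 5,
                                        effect_size = 6, seed = 1))
split  <- stratified_split(cohort, seed = 1)
fit <- svmga(split, config = ga_config(n_chromosomes = 200,
                                       max_generations = 150, seed = 1))
summary(fit)
#> Embedded GA-SVM feature selection
#>   dimensionality reduced 60 -> 7 features
#>   final fitness 1.0204 after 150 epochs
#>   accuracy: train 1.000, test 1.000, overall 1.000
#>   best fitness first reached at epoch 41 (of 150 run)
#>   fitness breakdown: FF1 = 1.0000, FF2 = 0.0058, FF3 = 0.0145
#>   margin width 3.44, 6 support vectors
#>   selected features:
#>     f01, f02, f21, f27, f30, f45, f55

cohort$feature_names[cohort$informative]
#> [1] "f02" "f21" "f27" "f30" "f45"
```

The selected subset contains all five planted features (plus two noise
features whose inclusion slightly widens the margin): the fitness settles
just above 1 — exactly 1 when the weights `a` and `b` are zero — with
perfect train, test, and overall accuracy, and `plot(fit)` draws the
four-curve trajectory (fit-value, train/test/overall accuracy,
dimensionality). The MI filter benchmark runs as

```r
sweep <- sequential_elimination_sweep(split, benchmark_spec("linear_svm"))
sweep
#> sweep_curve (linear_svm): 60 points, m in [1, 60]
#>   best test accuracy 1.000 at m = 60
```

End-to-end experiments (generate → split → sweeps → GA → artifacts) are
orchestrated by `run_experiment()` / `experiment_config()` (YAML-configurable
via `read_experiment_config()`), and a thin CLI over the same functions
lives at `inst/cli/svmga-cli.R` with subcommands `gen-cohort`,
`filter-sweep`, `ga-select`, `run-experiment`, and `summarize`.

See `vignettes/embedded-ga-svm.Rmd` for the model, its assumptions, the
design decisions, and the validation experiment sizes.

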