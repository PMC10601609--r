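---
title: "Embedded genetic-algorithm feature selection for SVM classifiers"
author: "svmga"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedded genetic-algorithm feature selection for SVM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmga)
```

## The problem

Clinical outcome prediction from physiological monitoring data routinely
produces tables with far more features than patients. The motivating setting
for this package is the prediction of periventricular leukomalacia (PVL), a
rare neonatal white-matter brain injury, from wavelet features of
postoperative vital-sign recordings: 56 neonates, 248 features per neonate,
32 positive outcomes, with 38 samples (23 positive / 15 negative) available
for training and 18 held out. At `n << d` a support vector machine will fit
the training set with almost any feature subset, so the scientific questions
are which small subset of features carries the signal, and how to select it
without consulting the held-out data.

Two families of selectors are implemented:

* a **filter benchmark**: rank features by mutual information (MI) with the
  outcome, select by threshold, and evaluate nested subsets by sequential
  elimination (`rank_features()`, `select_by_threshold()`,
  `sequential_elimination_sweep()`);
* the package's core, an **embedded wrapper**: a genetic algorithm (GA) over
  binary feature masks whose objective is built from the SVM's own geometry
  (`svmga()`, `run_ga()`).

## The model and its objective

For a candidate subset of `m` of the `d` features, a linear soft-margin SVM
is trained on the training split restricted to those features. Writing
`ACC_train` for its training accuracy and `width = 2 / ||w||_2` for the
geometric width of its separating margin (with `w = sum_i alpha_i y_i x_i`
the dual weight vector), the subset's fitness is

    FF = FF1 + FF2 + FF3
    FF1 = 1 / ACC_train
    FF2 = a * m / d
    FF3 = b / width

and the GA minimizes `FF`. `FF1` drives training accuracy to one, `FF2`
penalizes cardinality, and `FF3` prefers subsets in which the two classes
are separated by a wide margin — a proxy for generalization that never
touches the held-out data. Per-epoch test accuracy is recorded purely for
monitoring (`monitor_epoch()`); the acceptance property "poisoning the test
labels leaves the whole search trajectory bit-identical" is enforced by
interface (the fitness function receives only the training partition) and
verified by test.

Two published presentations of this objective are ambiguous, and the package
exposes both readings:

* **Cardinality term.** A literal `FF2 = a / m` *decreases* with subset
  size, which contradicts the term's declared purpose of minimizing the
  number of features. The default is therefore the normalized, increasing
  form `a * m / d`; `ff2_form = "literal_reciprocal"` restores the literal
  reading for fidelity experiments.
* **Margin term.** "`||w_m||`" is described both as the *width* of the
  separating plane and as the 2-norm of the weight vector; these differ
  (width `= 2 / ||w||_2`). Only the width reading makes minimizing `FF3`
  maximize the margin, so the default is `b / width`;
  `ff3_form = "reciprocal_weight_norm"` gives the literal `b / ||w||_2`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `a` | 0.05 | weight of the cardinality penalty (dimensionless) |
| `b` | 0.05 | weight of the inverse-margin penalty (units of 1/margin) |
| `C` | 1 | SVM soft-margin penalty; `1e6` approximates the hard margin |
| `n_chromosomes` | 1200 | GA population size |
| `max_generations` | 1005 | GA epoch cap |
| `crossover_rate` | 0.8 | probability of single-point crossover |
| `mutation_rate` | 0.01 | per-bit flip probability |
| `elitism` | 1 | best chromosomes copied unchanged each generation |

The population, generation, crossover, and mutation defaults are the
full-scale settings of the reference experiment the package's design
follows; all validation experiments in the package run scaled-down
configurations (documented below) because a full-scale run is a
multi-hour computation. The weight defaults `a = b = 0.05` keep
`FF2 + FF3 << FF1` near convergence, so a converged run settles at a
fit-value just above 1 — at exactly 1 when `a = b = 0`. With `a = b = 0`
the objective degenerates to training accuracy alone and no dimensionality
pressure exists; raising `a` is the lever that pushes the optimizer into
genuinely small subsets.

### Numerical choices

* **Standardization.** Each active feature is z-scored with *training-split*
  statistics before the dual solve; the same statistics transform test
  data. Margin widths are meaningless across subsets of heterogeneously
  scaled features, and wavelet-derived features have no common scale.
  Zero-variance features pass through uncentered rather than producing NaN.
* **Dual solver.** The dual problem is solved by libsvm (via e1071); the
  multipliers, weight vector, bias, and margin are reconstructed from the
  solution and checked against the dual constraints
  (`sum alpha_i y_i = 0`, `0 <= alpha_i <= C`) in the test suite, as well
  as against a brute-force maximum-margin grid search in two dimensions.
* **Degenerate evaluations.** A subset whose SVM has a zero weight vector
  (or zero training accuracy, or a solver failure) receives a finite
  penalty instead of raising: ten times the worst finite fitness of its
  generation inside the GA, a configurable constant (`1e6`) outside it.
  Empty masks are repaired (one random bit set), never evaluated.
* **Selection.** Parent selection is linear-rank by default: the best of
  `n` chromosomes is drawn with weight `n`, the worst with weight 1.
  Reciprocal-fitness roulette (`selection = "roulette"`) is also provided,
  but since converged fitness values cluster tightly in `[1, 1.1]`,
  reciprocal-fitness probabilities are nearly uniform and late-stage
  selection pressure vanishes; at desk-scale budgets (hundreds of
  chromosomes and generations) rank selection reaches the fitness optimum
  where roulette demonstrably stalls, which is why it is the default.
* **Ties.** MI ranking breaks ties by ascending feature index; kNN voting
  ties resolve to the nearest neighbour's label; cost tuning ties resolve
  to the smallest cost. Every code path is deterministic given the seeds.

## The synthetic cohort generator

The clinical dataset underlying the reference experiment is not publicly
deposited, so the package ships a seeded generator (`generate_cohort()`)
that emulates its structure: class-conditional multivariate Gaussian
features (the margin argument underlying `FF3` presumes approximately
normal classes), `n_samples = 56`, `d = 248`, 32 positives by default, and
a stratified 38/18 split fixed at 23/15 training positives/negatives.
A planted block of `n_informative` features differs between classes by
`effect_size` within-class standard deviations; the remaining features are
class-independent noise.

Two generator choices deserve justification:

* **Alternating shift signs.** The class-mean shift alternates in sign
  across the informative block (`+delta, -delta, ...`). For uncorrelated
  informative features this is immaterial (every planted feature still
  carries exactly `effect_size` sd of marginal signal). For an
  equicorrelated block (`correlation` close to 1) it concentrates the class
  signal in feature *contrasts*: each feature alone is weak while a
  difference of two features separates the classes strongly. This is the
  canonical structure in which marginal filters fail and subset-evaluating
  wrappers succeed, and it mimics redundant physiological channels whose
  informative content is relative rather than absolute.
* **Defaults for what the reference data does not state.** The marginal
  scale, correlation structure, and number of truly informative wavelet
  features of the clinical data are unknown; the generator defaults to
  10 informative features at effect size 1 with no correlation — a weak,
  realistic signal — and these defaults are deliberately left untouched by
  every experiment that needs stronger or structured signal (those pass
  explicit parameters).

What the generator does *not* emulate: heavy tails, heteroscedastic
channels, missingness, label noise, and the deterministic dependence among
wavelet coefficients of a single physiological signal. Passing tests on
this generator therefore validate the algorithms' mechanics and their
behaviour under the stated Gaussian assumptions, not clinical performance.

## Validation experiments and their sizes

The test suite runs every experiment at desk scale, chosen so the full
suite completes in minutes:

* **Exhaustive-oracle equivalence** at `d = 8`: all 255 subsets are
  enumerated and the GA (64 chromosomes, 50 generations) must find the
  global fitness minimum.
* **Settling fit-value**: on a separable cohort (5 informative of 60,
  effect size 6) with `a = b = 0`, the GA (100 x 100) reaches training
  accuracy 1 and fitness exactly 1.
* **Parameter recovery**: 5 informative of 60 at effect size 6, GA at
  200 chromosomes x 150 generations, three seeds; the selected subset must
  reach Jaccard overlap >= 0.6 with the planted block and >= 0.9 test
  accuracy, and the MI filter must rank all five planted features in its
  top decile.
* **Wrapper-vs-filter contrast**: 6 informative of 40 at effect size 0.5
  with block correlation 0.95 (marginally invisible, jointly ~7 sd), GA at
  200 x 200 with `a = 0.3`. The raised cardinality weight pushes the
  optimizer into the small-subset regime where noise-only masks cannot
  linearly separate 38 training samples but contrast pairs can — the
  regime where subset quality is combinatorial and a marginal ranking is
  uninformative. The GA's final test accuracy must exceed the filter
  sweep's test accuracy at the same subset size, per seed.

## Known limitations

* The margin criterion `FF3` rewards any direction of wide separation,
  including the spurious separability that high-dimensional noise provides
  at small `n`; it is informative only jointly with the cardinality
  pressure of `FF2`. Low-variance contrast signals are systematically
  under-rewarded by a geometric margin computed on z-scored features.
* With 18 held-out samples, test accuracies move in steps of 1/18; single
  splits are noisy, and the per-epoch test curve is a monitoring trace,
  not an unbiased performance estimate.
* The GA is stochastic; different seeds can select different (equally fit)
  subsets, especially among strongly correlated features. Reported runs
  fix all seeds.
* `a`, `b`, and `C` are not tuned automatically; they encode how strongly
  the analyst values parsimony and margin against training fit.
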