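test_that("a feature identical to the label attains the label entropy", {
  y <- c(rep(1, 32), rep(0, 24))
  h <- -(32 / 56 * log2(32 / 56) + 24 / 56 * log2(24 / 56))  # ~0.9852
  expect_equal(mutual_information(y, y), h, tolerance = 1e-12)
  expect_equal(h, 0.985228, tolerance = 1e-6)
})

test_that("an independent feature has near-zero estimated MI", {
  set.seed(31)
  y <- rbinom(2000, 1, 0.5)
  x <- rnorm(2000)
  # plug-in bias with 8 bins at n=2000 is ~ (bins-1)/(2n ln 2) ~ 0.0025 bits
  expect_lt(mutual_information(x, y), 0.01)
  expect_equal(mutual_information(rep(1, 2000), y), 0)  # constant feature
  expect_error(mutual_information(x, rep(1, 2000)), "single class")
})

test_that("MI matches the exhaustive contingency-table oracle", {
  set.seed(32)
  y <- rbinom(1000, 1, 0.5)
  x <- y; flip <- runif(1000) < 0.1; x[flip] <- 1 - x[flip]
  expect_equal(mutual_information(x, y), oracle_mi_table(x, y),
               tolerance = 1e-12)
  # and for a genuinely binned continuous feature
  z <- rnorm(1000) + 0.8 * y
  expect_equal(mutual_information(z, y, n_bins = 8),
               oracle_mi_table(svmga:::discretize_ef(z, 8), y),
               tolerance = 1e-12)
})

test_that("MI is bounded by the marginal entropies", {
  set.seed(33)
  for (i in 1:10) {
    n <- 200
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    x <- rnorm(n) + runif(1, 0, 2) * y
    mi <- mutual_information(x, y)
    H <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
    expect_gte(mi, 0)
    expect_lte(mi, min(H(svmga:::discretize_ef(x, 8)), H(y)) + 1e-12)
  }
})

test_that("planted features at effect 6 rank in the strongest decile", {
  fix <- make_planted_split(n_features = 60, n_informative = 5,
                            effect_size = 6, seed = 34)
  tr <- fix$split$train
  ranking <- rank_features(fix$cohort$X[tr, ], fix$cohort$y[tr])
  strongest <- rev(ranking$order)[1:6]  # top 10% of 60
  expect_true(all(fix$cohort$informative %in% strongest))
})

test_that("ranking is deterministic with index-ordered ties", {
  set.seed(35)
  X <- matrix(rnorm(56 * 6), 56, 6)
  X[, 4] <- X[, 2]  # duplicate column pair shares its MI value
  y <- rep(c(0, 1), 28)
  r1 <- rank_features(X, y)
  r2 <- rank_features(X, y)
  expect_identical(r1$order, r2$order)
  pos <- match(c(2, 4), r1$order)
  expect_equal(diff(pos), 1)      # adjacent
  expect_lt(pos[1], pos[2])       # ascending index on the tie
})

test_that("threshold selection behaves at its extremes and median", {
  fix <- make_planted_split(n_features = 20, seed = 36)
  tr <- fix$split$train
  ranking <- rank_features(fix$cohort$X[tr, ], fix$cohort$y[tr])
  expect_true(all(select_by_threshold(ranking, 0)))
  expect_false(any(select_by_threshold(ranking, max(ranking$mi) + 1e-9)))
  # roughly half retained at the median (binned MI values can tie)
  n_median <- sum(select_by_threshold(ranking, median(ranking$mi)))
  expect_gte(n_median, 8)
  expect_lte(n_median, 12)
})

test_that("the sweep records every dimensionality and never reads test labels", {
  fix <- make_planted_split(n_features = 12, n_informative = 2,
                            effect_size = 5, seed = 37)
  curve <- sequential_elimination_sweep(fix$split, benchmark_spec("knn"))
  expect_equal(nrow(curve), 12L)
  expect_identical(curve$m, seq(12L, 1L))
  expect_true(all(curve$train_acc >= 0 & curve$train_acc <= 1))
  # overall accuracy is the count over the union of both splits
  expect_equal(curve$overall_acc,
               (curve$train_acc * 38 + curve$test_acc * 18) / 56,
               tolerance = 1e-12)

  poisoned <- fix$split
  poisoned$data$y[poisoned$test] <- rev(poisoned$data$y[poisoned$test])
  curve_p <- sequential_elimination_sweep(poisoned, benchmark_spec("knn"))
  expect_identical(curve$train_acc, curve_p$train_acc)
  expect_identical(attr(curve, "ranking")$mi, attr(curve_p, "ranking")$mi)
})

test_that("the sweep tracks the planted signal on a separable cohort", {
  fix <- make_planted_split(n_features = 30, n_informative = 4,
                            effect_size = 6, seed = 38)
  curve <- sequential_elimination_sweep(fix$split, benchmark_spec("linear_svm"),
                                        step = 2)
  expect_gte(curve$test_acc[curve$m == 4], curve$test_acc[curve$m == 30])

  # the single strongest planted feature alone classifies well:
  # Bayes accuracy for a 6-sd shift is Phi(3) ~ 0.999
  expect_gt(curve$test_acc[curve$m == 1], 0.8)
})

test_that("an all-noise cohort yields chance-level test accuracy", {
  cohort <- generate_cohort(cohort_config(n_features = 15, n_informative = 0,
                                          seed = 39))
  split <- stratified_split(cohort, seed = 39)
  curve <- sequential_elimination_sweep(split, benchmark_spec("linear_svm"),
                                        step = 3)
  expect_lt(mean(curve$test_acc), 0.75)
  expect_gt(mean(curve$test_acc), 0.25)
})
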