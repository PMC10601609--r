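test_that("default generator reproduces the reference cohort shape", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  expect_equal(dim(cohort$X), c(56L, 248L))
  expect_equal(sum(cohort$y == 1L), 32L)
  expect_equal(sum(cohort$y == 0L), 24L)
  expect_false(anyNA(cohort$X))
  expect_false(anyDuplicated(cohort$feature_names) > 0)
})

test_that("generation is a pure function of the configuration", {
  a <- generate_cohort(cohort_config(n_features = 30, seed = 9))
  b <- generate_cohort(cohort_config(n_features = 30, seed = 9))
  c <- generate_cohort(cohort_config(n_features = 30, seed = 10))
  expect_identical(a$X, b$X)
  expect_identical(a$informative, b$informative)
  expect_false(identical(a$X, c$X))
  # generator must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_cohort(cohort_config(n_features = 10)))
  expect_identical(rnorm(1), before)
})

test_that("zero effect size leaves informative columns class-independent", {
  cohort <- generate_cohort(cohort_config(n_features = 100, n_informative = 10,
                                          effect_size = 0, seed = 3))
  diffs <- vapply(cohort$informative, function(j) {
    mean(cohort$X[cohort$y == 1L, j]) - mean(cohort$X[cohort$y == 0L, j])
  }, numeric(1))
  # mean class difference over 10 informative columns: sd ~ 0.27/sqrt(10)
  expect_lt(abs(mean(diffs)), 0.35)
})

test_that("planted features dominate the t-statistic spectrum at effect 6", {
  cohort <- generate_cohort(cohort_config(n_features = 248, n_informative = 5,
                                          effect_size = 6, seed = 4))
  tstat <- vapply(seq_len(248), function(j) {
    abs(stats::t.test(cohort$X[cohort$y == 1L, j],
                      cohort$X[cohort$y == 0L, j])$statistic)
  }, numeric(1))
  nuisance <- setdiff(seq_len(248), cohort$informative)
  cutoff <- stats::quantile(tstat[nuisance], 0.95)
  expect_true(all(tstat[cohort$informative] > cutoff))
})

test_that("nuisance columns carry no class signal in expectation", {
  cohort <- generate_cohort(cohort_config(n_features = 200, n_informative = 4,
                                          effect_size = 6, seed = 5))
  nuisance <- setdiff(seq_len(200), cohort$informative)
  tstat <- vapply(nuisance, function(j) {
    abs(stats::t.test(cohort$X[cohort$y == 1L, j],
                      cohort$X[cohort$y == 0L, j])$statistic)
  }, numeric(1))
  # mean |t| under the null is ~0.8 for ~54 df; far below 1.2 at n=196 columns
  expect_lt(mean(tstat), 1.2)
  expect_gt(mean(tstat), 0.5)
})

test_that("classification accuracy on informative columns rises with effect size", {
  accs <- vapply(c(0, 2, 6), function(es) {
    cohort <- generate_cohort(cohort_config(n_features = 40, n_informative = 5,
                                            effect_size = es, seed = 11))
    split <- stratified_split(cohort, seed = 11)
    keep <- cohort$informative
    model <- train_linear_svm(cohort$X[split$train, keep], cohort$y[split$train])
    accuracy(predict(model, cohort$X[split$test, keep]), cohort$y[split$test])
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_positive = 60), "n_positive")
  expect_error(cohort_config(n_informative = 300), "n_informative")
  expect_error(cohort_config(effect_size = -1), "effect_size")
  expect_error(cohort_config(correlation = 1), "correlation")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
})

test_that("stratified split reproduces the reference partition counts", {
  cohort <- generate_cohort(cohort_config(n_features = 10, seed = 2))
  split <- stratified_split(cohort, seed = 2)
  ytr <- cohort$y[split$train]; yte <- cohort$y[split$test]
  expect_length(split$train, 38L)
  expect_length(split$test, 18L)
  expect_equal(sum(ytr == 1L), 23L)
  expect_equal(sum(ytr == 0L), 15L)
  expect_equal(sum(yte == 1L), 9L)
  expect_equal(sum(yte == 0L), 9L)
  expect_length(intersect(split$train, split$test), 0L)
  expect_setequal(c(split$train, split$test), seq_len(56))
})

test_that("splitting is deterministic in its seed and validates counts", {
  cohort <- generate_cohort(cohort_config(n_features = 10, seed = 2))
  s1 <- stratified_split(cohort, seed = 5)
  s2 <- stratified_split(cohort, seed = 5)
  s3 <- stratified_split(cohort, seed = 6)
  expect_identical(s1$train, s2$train)
  expect_false(identical(s1$train, s3$train))
  expect_error(stratified_split(cohort, train_counts = c(pos = 33, neg = 15)),
               "train_counts")
  expect_error(stratified_split(cohort, train_counts = c(pos = 32, neg = 24)),
               "empty test set")
})
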