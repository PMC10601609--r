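test_that("roulette selection is proportional to reciprocal fitness", {
  pop <- rbind(c(1L, 0L), c(0L, 1L))
  set.seed(51)
  draws <- replicate(1e5, roulette_select(pop, c(1, 3))[1])
  # P(chromosome 1) = (1/1) / (1/1 + 1/3) = 0.75
  expect_equal(mean(draws == 1L), 0.75, tolerance = 0.01)

  draws_eq <- replicate(2e4, roulette_select(pop, c(2, 2))[1])
  expect_equal(mean(draws_eq == 1L), 0.5, tolerance = 0.02)

  single <- matrix(c(1L, 1L, 0L), 1)
  expect_equal(roulette_select(single, 5), c(1L, 1L, 0L))
  expect_error(roulette_select(pop[0, , drop = FALSE], numeric(0)), "empty")
  expect_error(roulette_select(pop, c(1, Inf)), "finite")
})

test_that("rank weights order chromosomes best-first regardless of scale", {
  w <- svmga:::rank_weights(c(1.027, 1.026, 5.0, 1.030))
  expect_equal(order(w, decreasing = TRUE), c(2, 1, 4, 3))
  expect_setequal(w, 1:4)
})

test_that("single-point crossover concatenates a prefix and a suffix", {
  x <- c(1L, 1L, 1L, 1L); y <- c(0L, 0L, 0L, 0L)
  cfg <- ga_config(crossover_rate = 1)
  set.seed(52)
  children <- unique(replicate(300, paste(reproduce(x, y, cfg), collapse = "")))
  expect_setequal(children, c("1000", "1100", "1110"))  # locus l in 1..3

  expect_equal(reproduce(x, x, cfg), x)
  expect_equal(reproduce(x, y, ga_config(crossover_rate = 0)), x)
  expect_error(reproduce(x, c(0L, 1L)), "equal length")
})

test_that("mutation flips bits at the configured rate and repairs empty masks", {
  mask <- c(1L, 0L, 1L, 0L)
  set.seed(53)
  expect_equal(mutate_mask(mask, 0), mask)
  expect_equal(mutate_mask(mask, 1), c(0L, 1L, 0L, 1L))

  big <- rep(c(1L, 0L), 124)  # d = 248
  flips <- replicate(1e4, sum(mutate_mask(big, 0.01) != big))
  expect_equal(mean(flips), 2.48, tolerance = 0.1)

  # a mask mutated to all-zero is repaired to cardinality 1
  repaired <- replicate(50, sum(mutate_mask(c(1L, 0L, 0L), 1)))
  expect_true(all(repaired >= 1))
})

test_that("the GA recovers the exhaustive-search optimum at d = 8", {
  cohort <- generate_cohort(cohort_config(n_features = 8, n_informative = 2,
                                          effect_size = 2, seed = 54))
  split <- stratified_split(cohort, seed = 54)
  cfg <- ga_config(n_chromosomes = 64, max_generations = 50, seed = 54)
  oracle <- oracle_best_subset(cohort$X[split$train, ], cohort$y[split$train],
                               d = 8, config = cfg)
  res <- run_ga(split, cfg)
  expect_equal(res$best_fitness$ff_total, oracle$ff, tolerance = 1e-10)
  expect_true(any(vapply(oracle$masks, identical, logical(1), res$best_mask)))
})

test_that("the trajectory is a pure function of data, config, and seed", {
  fix <- make_planted_split(n_features = 20, seed = 55)
  cfg <- small_ga_config()
  r1 <- run_ga(fix$split, cfg)
  r2 <- run_ga(fix$split, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$best_mask, r2$best_mask)
  r3 <- run_ga(fix$split, small_ga_config(seed = 8))
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("elitism makes the best-fitness trajectory non-increasing", {
  fix <- make_planted_split(n_features = 20, seed = 56)
  res <- run_ga(fix$split, small_ga_config(max_generations = 15))
  expect_true(all(diff(res$trajectory$best_ff) <= 1e-12))
  expect_true(all(is.finite(res$trajectory$best_ff)))
  expect_true(all(res$trajectory$best_ff > 0))
})

test_that("poisoning test labels cannot change the search trajectory", {
  fix <- make_planted_split(n_features = 20, seed = 57)
  cfg <- small_ga_config(max_generations = 12)
  clean <- run_ga(fix$split, cfg)

  poisoned_split <- fix$split
  yte <- poisoned_split$data$y[poisoned_split$test]
  poisoned_split$data$y[poisoned_split$test] <- rev(yte)
  poisoned <- run_ga(poisoned_split, cfg)

  expect_identical(clean$trajectory$best_ff, poisoned$trajectory$best_ff)
  expect_identical(clean$trajectory$m_best, poisoned$trajectory$m_best)
  expect_identical(clean$trajectory$train_acc, poisoned$trajectory$train_acc)
  expect_identical(clean$best_mask, poisoned$best_mask)
  expect_false(identical(clean$trajectory$test_acc, poisoned$trajectory$test_acc))
})

test_that("epoch monitoring counts accuracies over the right partitions", {
  fix <- make_planted_split(n_features = 10, n_informative = 3,
                            effect_size = 6, seed = 58)
  mask <- as.integer(seq_len(10) %in% fix$cohort$informative)
  model <- train_linear_svm(
    fix$cohort$X[fix$split$train, mask == 1L, drop = FALSE],
    fix$cohort$y[fix$split$train])
  rec <- monitor_epoch(model, mask, fix$split, epoch = 3, best_ff = 1.01)
  expect_equal(rec$epoch, 3)
  expect_equal(rec$m_best, 3L)
  # overall accuracy is the pooled count: (38 * train + 18 * test) / 56
  expect_equal(rec$overall_acc,
               (38 * rec$train_acc + 18 * rec$test_acc) / 56,
               tolerance = 1e-12)
  expect_equal((36 + 14) / 56, 50 / 56)  # e.g. 36/38 train and 14/18 test
})

test_that("early stopping triggers on the fitness target", {
  fix <- make_planted_split(n_features = 15, n_informative = 3,
                            effect_size = 6, seed = 59)
  cfg <- ga_config(n_chromosomes = 30, max_generations = 50, a = 0, b = 0,
                   ff_target = 1, seed = 59)
  res <- run_ga(fix$split, cfg)
  expect_lt(nrow(res$trajectory), 50)
  expect_equal(res$best_fitness$ff_total, 1)
})
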