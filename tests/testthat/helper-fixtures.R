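# Shared in-code fixtures. Everything is generated programmatically from
# fixed seeds; nothing is read from disk.

# A small, strongly separable planted-signal cohort + split.
make_planted_split <- function(n_features = 20, n_informative = 3,
                               effect_size = 4, correlation = 0, seed = 42,
                               split_seed = seed) {
  cohort <- generate_cohort(cohort_config(
    n_features = n_features, n_informative = n_informative,
    effect_size = effect_size, correlation = correlation, seed = seed))
  list(cohort = cohort,
       split = stratified_split(cohort, seed = split_seed))
}

# Two well-separated 2-D Gaussian clusters (always linearly separable).
make_separable_2d <- function(n_per_class = 10, gap = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(2 * n_per_class, mean = 0), ncol = 2),
             matrix(stats::rnorm(2 * n_per_class, mean = gap), ncol = 2))
  y <- rep(c(-1, 1), each = n_per_class)
  # reject draws that are not separable (gap = 4 sd makes this rare)
  stopifnot(oracle_max_margin_2d(X, y)$width > 0)
  list(X = X, y = y)
}

small_ga_config <- function(...) {
  args <- list(n_chromosomes = 40, max_generations = 10, seed = 7)
  user <- list(...)
  args[names(user)] <- user
  do.call(ga_config, args)
}
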