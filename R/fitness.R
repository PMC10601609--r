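#' Configuration of the embedded genetic algorithm
#'
#' Hyperparameters of the GA wrapper and of the three-term fitness function
#' it minimizes. The population/generation/rate defaults are the full-scale
#' settings reported for the reference experiment (1200 chromosomes, up to
#' 1005 generations, crossover 0.8, mutation 0.01); validation experiments
#' in this package run scaled-down versions.
#'
#' The fitness of a feature subset with mask cardinality `m`, training
#' accuracy `acc`, and geometric margin width `width` is
#' \deqn{FF = FF_1 + FF_2 + FF_3, \qquad FF_1 = 1/acc,}
#' with `FF2 = a * m / d` and `FF3 = b / width` under the default forms.
#' `FF2` penalizes subset cardinality and `FF3` penalizes a narrow
#' separating margin, so minimizing `FF` drives the model toward few
#' features, perfect training accuracy, and a wide margin. The literal
#' alternatives `ff2_form = "literal_reciprocal"` (`a/m`) and
#' `ff3_form = "reciprocal_weight_norm"` (`b/||w||_2`) are provided for
#' fidelity experiments; note `a/m` rewards larger subsets.
#'
#' @param n_chromosomes Population size (>= 2).
#' @param max_generations Generation cap.
#' @param crossover_rate Probability a child is produced by single-point
#'   crossover rather than copied from its first parent.
#' @param mutation_rate Per-bit flip probability.
#' @param a,b Non-negative weights of the cardinality and margin terms.
#' @param C Soft-margin penalty of the fitness SVM.
#' @param seed Integer seed; the full GA trajectory is a pure function of
#'   the data, the configuration, and this seed.
#' @param elitism Number of best chromosomes copied unchanged into the next
#'   generation (0 disables; the default 1 makes the best fitness
#'   trajectory monotone).
#' @param ff2_form,ff3_form Functional form of the cardinality and margin
#'   terms (see Details).
#' @param selection Parent-selection scheme. `"rank"` (default) uses linear
#'   ranking: the best of `n` chromosomes is drawn with weight `n`, the
#'   worst with weight 1. `"roulette"` draws with probability proportional
#'   to reciprocal fitness ([roulette_select()]); because converged fitness
#'   values cluster tightly above 1, reciprocal-fitness selection is close
#'   to uniform and gives very weak late-stage pressure, so it needs far
#'   larger population-generation budgets.
#' @param ff_target Stop early once the best fitness reaches this value
#'   (`NULL`: run all generations).
#' @param init_density Inclusion probability of each bit in the initial
#'   population.
#' @param standardize Z-score active features with training statistics
#'   inside each fitness evaluation.
#' @param degenerate_penalty Finite fitness assigned to a degenerate
#'   evaluation (zero training accuracy or zero weight vector) outside a GA
#'   generation; within [run_ga()] degenerate chromosomes instead receive
#'   10x the worst finite fitness of their generation.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(n_chromosomes = 1200, max_generations = 1005,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      a = 0.05, b = 0.05, C = 1, seed = 1, elitism = 1,
                      ff2_form = c("normalized_cardinality", "literal_reciprocal"),
                      ff3_form = c("reciprocal_margin_width", "reciprocal_weight_norm"),
                      selection = c("rank", "roulette"),
                      ff_target = NULL, init_density = 0.5,
                      standardize = TRUE, degenerate_penalty = 1e6) {
  cfg <- list(
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes", min = 2L),
    max_generations = check_count(max_generations, "max_generations"),
    crossover_rate = check_real(crossover_rate, "crossover_rate", 0, 1),
    mutation_rate = check_real(mutation_rate, "mutation_rate", 0, 1),
    a = check_real(a, "a", lower = 0),
    b = check_real(b, "b", lower = 0),
    C = check_real(C, "C", lower = 0, lower_open = TRUE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max),
    elitism = check_count(elitism, "elitism", min = 0L),
    ff2_form = match.arg(ff2_form),
    ff3_form = match.arg(ff3_form),
    selection = match.arg(selection),
    ff_target = if (is.null(ff_target)) NULL else
      check_real(ff_target, "ff_target", lower = 0),
    init_density = check_real(init_density, "init_density", 0, 1,
                              lower_open = TRUE),
    standardize = isTRUE(standardize),
    degenerate_penalty = check_real(degenerate_penalty, "degenerate_penalty",
                                    lower = 0, lower_open = TRUE)
  )
  structure(cfg, class = "ga_config")
}

# Pure arithmetic of the three-term objective; kept separate from the SVM
# training so it is testable in isolation.
ff_combine <- function(acc_train, m, d, width, w_norm, config) {
  ff1 <- 1 / acc_train
  ff2 <- switch(config$ff2_form,
                normalized_cardinality = config$a * m / d,
                literal_reciprocal = config$a / m)
  ff3 <- switch(config$ff3_form,
                reciprocal_margin_width = config$b / width,
                reciprocal_weight_norm = config$b / w_norm)
  list(ff1 = ff1, ff2 = ff2, ff3 = ff3, ff_total = ff1 + ff2 + ff3)
}

#' Evaluate the fitness of one feature subset
#'
#' Trains a linear SVM on the training data restricted to the active
#' features of `mask` and assembles the three-term fitness (see
#' [ga_config()]). Only training rows may be passed in: the fitness is
#' test-blind by construction.
#'
#' A degenerate evaluation -- zero training accuracy, a zero weight vector,
#' or a solver failure -- never raises; it returns a breakdown flagged
#' `degenerate = TRUE` whose total equals `config$degenerate_penalty`.
#'
#' @param mask Binary (0/1 or logical) inclusion vector over all `d`
#'   features; at least one active feature.
#' @param x_train Training feature matrix (all `d` columns).
#' @param y_train Binary training labels.
#' @param config A [ga_config()].
#' @return An object of class `"fitness_breakdown"`: list with `ff1`,
#'   `ff2`, `ff3`, `ff_total`, `acc_train`, `m`, `margin`, `degenerate`,
#'   and the trained `model`.
#' @export
evaluate_fitness <- function(mask, x_train, y_train, config = ga_config()) {
  mask <- as.logical(mask)
  m <- sum(mask)
  if (m < 1L) stop("empty feature subset cannot be evaluated", call. = FALSE)
  d <- length(mask)
  x_train <- as.matrix(x_train)
  if (ncol(x_train) != d) {
    stop("mask length must equal ncol(x_train)", call. = FALSE)
  }
  res <- tryCatch({
    model <- train_linear_svm(x_train[, mask, drop = FALSE], y_train,
                              C = config$C, standardize = config$standardize)
    acc <- accuracy(predict(model, x_train[, mask, drop = FALSE]), y_train)
    if (model$degenerate || acc <= 0) {
      list(model = model, acc = acc, degenerate = TRUE)
    } else {
      list(model = model, acc = acc, degenerate = FALSE)
    }
  }, error = function(e) list(model = NULL, acc = NA_real_, degenerate = TRUE))

  if (res$degenerate) {
    out <- list(ff1 = NA_real_, ff2 = NA_real_, ff3 = NA_real_,
                ff_total = config$degenerate_penalty,
                acc_train = res$acc, m = m, margin = NA_real_,
                degenerate = TRUE, model = res$model)
  } else {
    width <- margin_width(res$model)
    parts <- ff_combine(res$acc, m, d, width, res$model$w_norm, config)
    out <- c(parts, list(acc_train = res$acc, m = m, margin = width,
                         degenerate = FALSE, model = res$model))
  }
  structure(out, class = "fitness_breakdown")
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("fitness_breakdown: DEGENERATE (penalty %.4g), m = %d\n",
                x$ff_total, x$m))
  } else {
    cat(sprintf(
      "fitness_breakdown: FF = %.4f (FF1 = %.4f, FF2 = %.4f, FF3 = %.4f)\n",
      x$ff_total, x$ff1, x$ff2, x$ff3))
    cat(sprintf("  train accuracy %.3f, m = %d, margin width %.4g\n",
                x$acc_train, x$m, x$margin))
  }
  invisible(x)
}
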