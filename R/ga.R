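#' Roulette-wheel selection under minimization
#'
#' Draws one chromosome from the population with probability proportional
#' to the reciprocal of its fitness (the objective is minimized, so smaller
#' fitness must mean larger selection probability). Uses the current RNG
#' stream.
#'
#' @param population Integer 0/1 matrix, one chromosome per row.
#' @param fitness Vector of finite positive fitness values, one per row.
#' @return The selected chromosome (integer 0/1 vector).
#' @export
roulette_select <- function(population, fitness) {
  population <- as.matrix(population)
  if (nrow(population) == 0L) stop("empty population", call. = FALSE)
  if (length(fitness) != nrow(population)) {
    stop("one fitness value per chromosome required", call. = FALSE)
  }
  if (any(!is.finite(fitness)) || any(fitness <= 0)) {
    stop("fitness values must be finite and positive", call. = FALSE)
  }
  population[roulette_index(fitness), ]
}

roulette_index <- function(fitness) {
  w <- 1 / fitness
  sample.int(length(fitness), 1L, prob = w)
}

# Linear ranking: weight n for the best chromosome down to 1 for the worst.
# Ties share the ordering given by order()'s stable sort.
rank_weights <- function(fitness) {
  n <- length(fitness)
  w <- numeric(n)
  w[order(fitness)] <- n:1
  w
}

#' Single-point crossover
#'
#' With probability `config$crossover_rate` the child is the concatenation
#' of a prefix of `x` and the complementary suffix of `y`, with the locus
#' drawn uniformly from the `d - 1` interior cut points; otherwise the
#' child is a copy of `x`. Uses the current RNG stream.
#'
#' @param x,y Parent chromosomes (equal-length 0/1 vectors).
#' @param config A [ga_config()] (only `crossover_rate` is used).
#' @return Child chromosome.
#' @export
reproduce <- function(x, y, config = ga_config()) {
  if (length(x) != length(y)) {
    stop("parent chromosomes must have equal length", call. = FALSE)
  }
  d <- length(x)
  if (d >= 2L && stats::runif(1) < config$crossover_rate) {
    l <- sample.int(d - 1L, 1L)
    c(x[seq_len(l)], y[(l + 1L):d])
  } else {
    x
  }
}

#' Bit-flip mutation with empty-mask repair
#'
#' Flips each bit independently with probability `rate`. A result with no
#' active features is repaired by switching one uniformly chosen bit on, so
#' an empty subset is never evaluated. Uses the current RNG stream.
#'
#' @param mask Chromosome (0/1 vector).
#' @param rate Per-bit flip probability in `[0, 1]`.
#' @return Mutated chromosome.
#' @export
mutate_mask <- function(mask, rate) {
  rate <- check_real(rate, "rate", 0, 1)
  flip <- stats::runif(length(mask)) < rate
  out <- ifelse(flip, 1L - mask, mask)
  if (sum(out) == 0L) out[sample.int(length(out), 1L)] <- 1L
  as.integer(out)
}

#' Per-epoch monitoring record
#'
#' Evaluates the epoch's best SVM on the training, testing, and combined
#' samples. Monitoring is one-way: nothing computed here feeds back into
#' the genetic search, so the test split never influences the selection.
#'
#' @param model The epoch-best `"linear_svm"`.
#' @param mask Its feature mask.
#' @param split The [stratified_split()] the GA runs on.
#' @param epoch Epoch number.
#' @param best_ff Best fitness value of the epoch.
#' @return One-row data frame: `epoch`, `best_ff`, `train_acc`, `test_acc`,
#'   `overall_acc`, `m_best`.
#' @export
monitor_epoch <- function(model, mask, split, epoch, best_ff) {
  mask <- as.logical(mask)
  X <- split$data$X; y <- split$data$y
  pred_tr <- predict(model, X[split$train, mask, drop = FALSE])
  pred_te <- predict(model, X[split$test, mask, drop = FALSE])
  n_tr <- sum(pred_tr == y[split$train])
  n_te <- sum(pred_te == y[split$test])
  data.frame(epoch = epoch, best_ff = best_ff,
             train_acc = n_tr / length(split$train),
             test_acc = n_te / length(split$test),
             overall_acc = (n_tr + n_te) / length(y),
             m_best = sum(mask))
}

#' Run the embedded genetic-algorithm feature search
#'
#' Generational GA over binary feature masks. Each generation every
#' chromosome is scored by [evaluate_fitness()] on the training split only;
#' parents are drawn by linear-rank selection (or reciprocal-fitness
#' roulette, see [ga_config()]), children by single-point [reproduce()] crossover and
#' [mutate_mask()] bit flips, with `elitism` copies of the generation's best
#' chromosomes carried over unchanged. After each generation the best
#' chromosome's SVM is evaluated on the test split for the trajectory
#' record only. The run stops at `max_generations` or as soon as the best
#' fitness reaches `ff_target`.
#'
#' Fitness evaluations are cached by mask, which changes nothing numerically
#' (the fitness is deterministic in the mask) but makes converged
#' populations cheap. Degenerate chromosomes receive ten times the worst
#' finite fitness of their generation.
#'
#' @param split A [stratified_split()].
#' @param config A [ga_config()].
#' @return List with `best_mask` (integer 0/1 vector), `best_fitness`
#'   (its [evaluate_fitness()] breakdown), `best_model` (its trained
#'   `"linear_svm"`), `trajectory` (data frame of [monitor_epoch()] rows),
#'   `n_evaluations` (unique masks evaluated), and `config`.
#' @export
run_ga <- function(split, config = ga_config()) {
  stopifnot(inherits(split, "split_dataset"), inherits(config, "ga_config"))
  X <- split$data$X
  x_train <- X[split$train, , drop = FALSE]
  y_train <- split$data$y[split$train]
  d <- ncol(X)
  nc <- config$n_chromosomes

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  eval_mask <- function(mask) {
    key <- rawToChar(as.raw(44L + mask))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fb <- evaluate_fitness(mask, x_train, y_train, config)
    cache[[key]] <- fb
    fb
  }

  with_seed(config$seed, {
    pop <- matrix(as.integer(stats::runif(nc * d) < config$init_density), nc, d)
    empty <- rowSums(pop) == 0L
    for (i in which(empty)) pop[i, sample.int(d, 1L)] <- 1L

    trajectory <- vector("list", config$max_generations)
    best_fb <- NULL; best_mask <- NULL; best_val <- Inf

    for (gen in seq_len(config$max_generations)) {
      evals <- lapply(seq_len(nc), function(i) eval_mask(pop[i, ]))
      raw_ff <- vapply(evals, `[[`, numeric(1), "ff_total")
      degen <- vapply(evals, `[[`, logical(1), "degenerate")
      ff <- raw_ff
      if (any(degen)) {
        worst <- if (all(degen)) config$degenerate_penalty else
          max(raw_ff[!degen])
        ff[degen] <- 10 * worst
      }
      ord <- order(ff)
      gen_best <- ord[1L]
      if (ff[gen_best] < best_val) {
        best_val <- ff[gen_best]
        best_fb <- evals[[gen_best]]
        best_mask <- pop[gen_best, ]
      }
      trajectory[[gen]] <- if (evals[[gen_best]]$degenerate) {
        data.frame(epoch = gen, best_ff = ff[gen_best], train_acc = NA_real_,
                   test_acc = NA_real_, overall_acc = NA_real_,
                   m_best = sum(pop[gen_best, ]))
      } else {
        monitor_epoch(evals[[gen_best]]$model, pop[gen_best, ], split,
                      epoch = gen, best_ff = ff[gen_best])
      }
      if (!is.null(config$ff_target) && ff[gen_best] <= config$ff_target) {
        trajectory <- trajectory[seq_len(gen)]
        break
      }
      if (gen == config$max_generations) break

      new_pop <- matrix(0L, nc, d)
      n_elite <- min(config$elitism, nc)
      if (n_elite > 0L) {
        new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      }
      sel_w <- if (config$selection == "rank") rank_weights(ff) else 1 / ff
      for (i in seq.int(n_elite + 1L, nc)) {
        px <- pop[sample.int(nc, 1L, prob = sel_w), ]
        py <- pop[sample.int(nc, 1L, prob = sel_w), ]
        child <- reproduce(px, py, config)
        new_pop[i, ] <- mutate_mask(child, config$mutation_rate)
      }
      pop <- new_pop
    }

    list(best_mask = as.integer(best_mask),
         best_fitness = best_fb,
         best_model = best_fb$model,
         trajectory = do.call(rbind, trajectory),
         n_evaluations = length(ls(cache)),
         config = config)
  })
}
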