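# Independent oracles used to validate the package's solvers. They share no
# code with the implementation paths they check.

# Brute-force maximum-margin search in 2-D: scan hyperplane directions on a
# fine angular grid, refine the best with golden-section search. For a
# direction u, the widest slab separating the classes has width
# min_{+}(x.u) - max_{-}(x.u); the maximum over directions is the
# hard-margin width.
oracle_max_margin_2d <- function(X, y_pm) {
  gap <- function(theta) {
    u <- c(cos(theta), sin(theta))
    p <- X %*% u
    min(p[y_pm > 0]) - max(p[y_pm < 0])
  }
  thetas <- seq(0, 2 * pi, length.out = 20001L)
  gaps <- vapply(thetas, gap, numeric(1))
  i <- which.max(gaps)
  step <- thetas[2L] - thetas[1L]
  opt <- stats::optimize(gap, interval = thetas[i] + c(-step, step),
                         maximum = TRUE, tol = 1e-12)
  list(width = opt$objective,
       normal = c(cos(opt$maximum), sin(opt$maximum)))
}

# Plug-in mutual information from an explicit contingency table, via the
# entropy decomposition I(X;Y) = H(X) + H(Y) - H(X,Y).
oracle_mi_table <- function(x_discrete, y) {
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  H(x_discrete) + H(y) - H(paste(x_discrete, y))
}

# Exhaustive enumeration of all non-empty feature subsets at small d.
oracle_best_subset <- function(x_train, y_train, d, config) {
  best_ff <- Inf; best_masks <- list()
  for (code in seq_len(2^d - 1L)) {
    mask <- as.integer(intToBits(code)[seq_len(d)] == 1)
    ff <- evaluate_fitness(mask, x_train, y_train, config)$ff_total
    if (ff < best_ff - 1e-12) {
      best_ff <- ff; best_masks <- list(mask)
    } else if (abs(ff - best_ff) <= 1e-12) {
      best_masks <- c(best_masks, list(mask))
    }
  }
  list(ff = best_ff, masks = best_masks)
}
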