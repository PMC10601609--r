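#' Specification of a benchmark classifier
#'
#' The filter-method benchmark evaluates its feature rankings with four
#' fixed reference classifiers: a pruned decision tree (at most 13 internal
#' "parent" nodes), an RBF-kernel SVM with \eqn{\gamma = 1/m} where `m` is
#' the number of features used, a linear SVM with an internally tuned cost,
#' and an unweighted Euclidean 4-nearest-neighbour vote.
#'
#' @param kind One of `"simple_tree"`, `"rbf_svm"`, `"linear_svm"`, `"knn"`.
#' @param max_parents Tree only: cap on internal (split) nodes.
#' @param k kNN only: neighbourhood size.
#' @param cost_grid Linear SVM only: candidate costs for internal 5-fold
#'   cross-validation; ties resolve to the smallest cost.
#' @param seed Seed for the deterministic cross-validation folds.
#' @return An object of class `"benchmark_spec"`.
#' @export
benchmark_spec <- function(kind = c("simple_tree", "rbf_svm", "linear_svm", "knn"),
                           max_parents = 13, k = 4,
                           cost_grid = c(0.01, 0.1, 1, 10, 100), seed = 1) {
  kind <- match.arg(kind)
  structure(list(
    kind = kind,
    max_parents = check_count(max_parents, "max_parents"),
    k = check_count(k, "k"),
    cost_grid = vapply(cost_grid, check_real, numeric(1), field = "cost_grid",
                       lower = 0, lower_open = TRUE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "benchmark_spec")
}

#' Train one of the four benchmark classifiers
#'
#' All kinds z-score features with training statistics (harmless for the
#' tree, essential for the distance- and margin-based kinds). Predictions on
#' new data reuse the stored statistics.
#'
#' @param spec A [benchmark_spec()].
#' @param X Training feature matrix.
#' @param y Binary training labels (`{0,1}` or `{-1,+1}`).
#' @return An object of class `"benchmark_classifier"` with a
#'   [predict.benchmark_classifier()] method.
#' @export
train_benchmark_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "benchmark_spec"))
  X <- as.matrix(X)
  coding <- label_coding(y)
  y_pm <- labels_to_pm1(y)
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[!is.finite(scale_) | scale_ < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  yf <- factor(y_pm, levels = c(-1, 1))

  fit <- switch(spec$kind,
    simple_tree = {
      df <- data.frame(Xs, check.names = FALSE)
      tr <- rpart::rpart(yf ~ ., data = cbind(df, yf = yf), method = "class",
                         control = rpart::rpart.control(
                           minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                           maxsurrogate = 0))
      cp <- tr$cptable
      ok <- cp[, "nsplit"] <= spec$max_parents
      # prune back to the largest tree within the parent-node cap
      rpart::prune(tr, cp = cp[max(which(ok)), "CP"])
    },
    rbf_svm = e1071::svm(Xs, yf, type = "C-classification", kernel = "radial",
                         gamma = 1 / ncol(Xs), cost = 1, scale = FALSE),
    linear_svm = {
      best <- tune_linear_cost(Xs, yf, spec$cost_grid, spec$seed)
      e1071::svm(Xs, yf, type = "C-classification", kernel = "linear",
                 cost = best, scale = FALSE)
    },
    knn = list(X = Xs, y = y_pm, k = spec$k)
  )
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 center = center, scale = scale_, label_coding = coding),
            class = "benchmark_classifier")
}

# 5-fold CV over the cost grid; deterministic folds, ties -> smallest cost.
tune_linear_cost <- function(Xs, yf, grid, seed) {
  n <- nrow(Xs)
  folds <- with_seed(seed, sample(rep_len(seq_len(min(5L, n)), n)))
  err <- vapply(grid, function(cost) {
    mean(vapply(unique(folds), function(f) {
      hold <- folds == f
      if (length(unique(yf[!hold])) < 2L) return(NA_real_)
      m <- e1071::svm(Xs[!hold, , drop = FALSE], yf[!hold],
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
      mean(predict(m, Xs[hold, , drop = FALSE]) != yf[hold])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[which.min(err)]
}

#' @rdname train_benchmark_classifier
#' @param object A `"benchmark_classifier"`.
#' @param newdata Feature matrix over the training features.
#' @param ... Unused.
#' @export
predict.benchmark_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  pred_pm <- switch(object$kind,
    simple_tree = {
      df <- data.frame(Xs, check.names = FALSE)
      as.numeric(as.character(predict(object$fit, df, type = "class")))
    },
    rbf_svm = ,
    linear_svm = as.numeric(as.character(predict(object$fit, Xs))),
    knn = knn_predict(object$fit, Xs)
  )
  pm1_to_coding(pred_pm, object$label_coding)
}

# Unweighted Euclidean kNN with a deterministic tie rule: a tied vote goes
# to the label of the single nearest neighbour.
knn_predict <- function(fit, Xs) {
  apply(Xs, 1L, function(q) {
    d2 <- colSums((t(fit$X) - q)^2)
    nn <- order(d2, seq_along(d2))[seq_len(fit$k)]
    vote <- sum(fit$y[nn])
    if (vote > 0) 1 else if (vote < 0) -1 else fit$y[nn[1L]]
  })
}

#' @export
print.benchmark_classifier <- function(x, ...) {
  cat(sprintf("benchmark_classifier: %s\n", x$kind))
  invisible(x)
}
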