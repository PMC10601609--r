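#' Embedded GA feature selection for a linear SVM classifier
#'
#' Fits the package's core model: a genetic algorithm searches binary
#' feature masks, scoring each candidate subset by the three-term fitness
#' \eqn{FF = 1/ACC_{train} + a\,m/d + b/\mathrm{width}} of a linear SVM
#' trained on the subset (see [ga_config()]), and returns the
#' minimum-fitness subset together with its SVM. The test split is used
#' only to monitor generalization along the optimization trajectory; it
#' never influences the search.
#'
#' @param x Feature matrix (samples x features), or a [feature_dataset()],
#'   or a [stratified_split()] (in which case `y` and the split arguments
#'   are ignored).
#' @param y Binary labels (`{0,1}`), required when `x` is a plain matrix.
#' @param config A [ga_config()].
#' @param train_counts,split_seed Passed to [stratified_split()] when `x`
#'   is not already split.
#' @param ... Unused.
#' @return An object of class `"svmga"`: list with `best_mask`, `m`
#'   (selected cardinality), `d`, `features` (selected feature names),
#'   `fitness` (final [evaluate_fitness()] breakdown), `model` (the final
#'   `"linear_svm"`), `trajectory`, `split`, `config`, `accuracies`
#'   (train/test/overall of the final model), and `call`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_features = 30, n_informative = 3,
#'                                         effect_size = 4, seed = 2))
#' fit <- svmga(cohort, config = ga_config(n_chromosomes = 30,
#'                                         max_generations = 10, seed = 2))
#' print(fit)
#' @export
svmga <- function(x, ...) UseMethod("svmga")

#' @rdname svmga
#' @export
svmga.default <- function(x, y, config = ga_config(),
                          train_counts = c(pos = 23, neg = 15),
                          split_seed = 1, ...) {
  dataset <- feature_dataset(x, y)
  svmga.feature_dataset(dataset, config = config, train_counts = train_counts,
                        split_seed = split_seed)
}

#' @rdname svmga
#' @export
svmga.feature_dataset <- function(x, config = ga_config(),
                                  train_counts = c(pos = 23, neg = 15),
                                  split_seed = 1, ...) {
  split <- stratified_split(x, train_counts = train_counts, seed = split_seed)
  svmga.split_dataset(split, config = config)
}

#' @rdname svmga
#' @export
svmga.split_dataset <- function(x, config = ga_config(), ...) {
  cl <- match.call()
  ga <- run_ga(x, config)
  mask <- as.logical(ga$best_mask)
  traj <- ga$trajectory
  final <- monitor_epoch(ga$best_model, ga$best_mask, x,
                         epoch = nrow(traj), best_ff = ga$best_fitness$ff_total)
  structure(list(
    best_mask = ga$best_mask,
    m = sum(mask),
    d = length(mask),
    features = x$data$feature_names[mask],
    fitness = ga$best_fitness,
    model = ga$best_model,
    trajectory = traj,
    split = x,
    config = config,
    accuracies = c(train = final$train_acc, test = final$test_acc,
                   overall = final$overall_acc),
    n_evaluations = ga$n_evaluations,
    call = cl
  ), class = "svmga")
}

#' @export
print.svmga <- function(x, ...) {
  cat("Embedded GA-SVM feature selection\n")
  cat(sprintf("  dimensionality reduced %d -> %d features\n", x$d, x$m))
  cat(sprintf("  final fitness %.4f after %d epochs\n",
              x$fitness$ff_total, nrow(x$trajectory)))
  cat(sprintf("  accuracy: train %.3f, test %.3f, overall %.3f\n",
              x$accuracies["train"], x$accuracies["test"],
              x$accuracies["overall"]))
  invisible(x)
}

#' @export
summary.svmga <- function(object, ...) {
  conv <- which(object$trajectory$best_ff <=
                  min(object$trajectory$best_ff) + 1e-12)[1L]
  structure(list(fit = object, convergence_epoch = conv),
            class = "summary.svmga")
}

#' @export
print.summary.svmga <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  best fitness first reached at epoch %d (of %d run)\n",
              x$convergence_epoch, nrow(x$fit$trajectory)))
  fb <- x$fit$fitness
  cat(sprintf("  fitness breakdown: FF1 = %.4f, FF2 = %.4f, FF3 = %.4f\n",
              fb$ff1, fb$ff2, fb$ff3))
  cat(sprintf("  margin width %.4g, %d support vectors\n",
              fb$margin, length(x$fit$model$support)))
  cat("  selected features:\n")
  cat(strwrap(paste(x$fit$features, collapse = ", "), width = 70,
              indent = 4, exdent = 4), sep = "\n")
  invisible(x)
}

#' @export
#' @rdname svmga
#' @param object A fitted `"svmga"` model.
coef.svmga <- function(object, ...) {
  # Map the standardized-scale hyperplane back to the input scale:
  # w.(x - c)/s + b  =  (w/s).x + (b - sum(w c / s))
  m <- object$model
  w <- m$w / m$scale
  b <- m$bias - sum(m$w * m$center / m$scale)
  c("(bias)" = b, w)
}

#' @export
#' @rdname svmga
#' @param newdata Matrix over either all `d` original features or exactly
#'   the `m` selected ones.
predict.svmga <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == object$d) {
    newdata <- newdata[, as.logical(object$best_mask), drop = FALSE]
  } else if (ncol(newdata) != object$m) {
    stop(sprintf("newdata must have %d (all) or %d (selected) columns",
                 object$d, object$m), call. = FALSE)
  }
  predict(object$model, newdata)
}

#' @export
fitted.svmga <- function(object, ...) {
  X <- object$split$data$X[object$split$train, , drop = FALSE]
  predict(object, X)
}

#' Plot the optimization trajectory of a fitted svmga model
#'
#' Draws the epoch-wise best fitness value together with the training,
#' testing, and overall accuracy of the epoch-best model (left axis) and
#' the selected dimensionality (right axis) -- the standard four-curve
#' trajectory view of the embedded wrapper.
#'
#' @param x A fitted `"svmga"` model.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.svmga <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(graphics::par(op))
  ylim <- c(0, max(2, max(tr$best_ff)))
  graphics::plot(tr$epoch, tr$best_ff, type = "l", lwd = 2, ylim = ylim,
                 xlab = "Epoch", ylab = "Fit-value / accuracy",
                 main = "Embedded GA feature optimization", ...)
  graphics::lines(tr$epoch, tr$train_acc, lty = 3, col = "blue")
  graphics::lines(tr$epoch, tr$test_acc, lty = 3, col = "red")
  graphics::lines(tr$epoch, tr$overall_acc, lty = 1, col = "red")
  graphics::par(new = TRUE)
  graphics::plot(tr$epoch, tr$m_best, type = "l", col = "darkgreen", lwd = 2,
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, x$d))
  graphics::axis(4)
  graphics::mtext("Dimensionality (m)", side = 4, line = 3)
  graphics::legend("topright", bty = "n", cex = 0.8,
                   legend = c("fit-value", "train acc", "test acc",
                              "overall acc", "m"),
                   col = c("black", "blue", "red", "red", "darkgreen"),
                   lty = c(1, 3, 3, 1, 1), lwd = c(2, 1, 1, 1, 2))
  invisible(x)
}
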