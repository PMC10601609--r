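#' Train a linear soft-margin SVM and expose its dual solution
#'
#' Solves the dual maximum-margin problem
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i\alpha_j
#'   y_i y_j (x_i \cdot x_j), \quad 0 \le \alpha_i \le C,\ \sum_i \alpha_i y_i = 0}
#' and reconstructs the separating hyperplane \eqn{w = \sum_i \alpha_i y_i x_i}
#' and bias from the multipliers, so that the geometric margin width
#' \eqn{2/\|w\|_2} is available to the feature-selection fitness function.
#'
#' Features are, by default, z-scored with statistics of the supplied
#' (training) data before the solve; margin comparisons across feature
#' subsets are meaningless on heterogeneously scaled features. Prediction on
#' new data reuses the stored statistics. Zero-variance features are left
#' uncentered-unscaled rather than producing NaN.
#'
#' @param X Numeric matrix (samples x active features).
#' @param y Binary labels, `{0,1}` or `{-1,+1}`; both classes required.
#' @param C Soft-margin penalty; `C = 1e6` approximates the hard margin.
#' @param standardize Z-score features with training statistics first.
#' @return An object of class `"linear_svm"`: list with `alphas` (length-n
#'   vector of Lagrange multipliers), `support` (indices with alpha > 0),
#'   `w` (weight vector, on the standardized scale when `standardize = TRUE`),
#'   `bias`, `w_norm`, `margin_width` (`2 / w_norm`; `Inf` when degenerate),
#'   `degenerate` (logical: zero weight vector), `C`, and the scaling
#'   statistics.
#' @examples
#' m <- train_linear_svm(matrix(c(1, -1)), c(1, 0), C = 1e6, standardize = FALSE)
#' c(m$w, m$bias, m$margin_width)  # 1, 0, 2
#' @export
train_linear_svm <- function(X, y, C = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  coding <- label_coding(y)
  y_pm <- labels_to_pm1(y)
  if (nrow(X) != length(y_pm)) stop("nrow(X) must equal length(y)", call. = FALSE)
  C <- check_real(C, "C", lower = 0, lower_open = TRUE)

  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[!is.finite(scale_) | scale_ < .Machine$double.eps] <- 1
    Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  } else {
    center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
    Xs <- X
  }

  yf <- factor(y_pm, levels = c(-1, 1))
  # libsvm's default working tolerance (1e-3) leaves hard-margin solutions
  # visibly short of the optimum; tighten it for accurate margin geometry.
  fit <- e1071::svm(Xs, yf, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-6)
  # libsvm's decision value is w.x - rho, positive for the class listed
  # first in fit$labels; flip so positive always means y = +1.
  w <- drop(crossprod(fit$coefs, fit$SV))
  bias <- -fit$rho
  if (fit$levels[fit$labels[1L]] != "1") {
    w <- -w; bias <- -bias
  }
  alphas <- numeric(nrow(X))
  alphas[fit$index] <- abs(drop(fit$coefs))
  w_norm <- sqrt(sum(w^2))
  degenerate <- w_norm < 1e-10
  names(w) <- colnames(X)

  structure(list(
    alphas = alphas,
    support = sort(fit$index),
    w = w, bias = bias,
    w_norm = w_norm,
    margin_width = if (degenerate) Inf else 2 / w_norm,
    degenerate = degenerate,
    C = C,
    center = center, scale = scale_, standardize = standardize,
    label_coding = coding,
    n_train = nrow(X)
  ), class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("linear_svm: %d features, %d support vectors, C = %g\n",
              length(x$w), length(x$support), x$C))
  if (x$degenerate) cat("  DEGENERATE: zero weight vector\n")
  else cat(sprintf("  ||w|| = %.4g, margin width = %.4g\n", x$w_norm, x$margin_width))
  invisible(x)
}

#' Decision-boundary weight vector of a trained SVM
#'
#' Returns the hyperplane normal \eqn{w = \sum_i \alpha_i y_i x_i} summed over
#' the support vectors, of dimension equal to the active-subset cardinality.
#' A degenerate model (all multipliers cancelling) returns the zero vector
#' with a warning.
#'
#' @param model A `"linear_svm"` from [train_linear_svm()].
#' @return Numeric weight vector.
#' @export
decision_boundary <- function(model) {
  if (!inherits(model, "linear_svm")) {
    stop("decision_boundary() requires a trained linear_svm", call. = FALSE)
  }
  if (model$degenerate) warning("degenerate model: zero weight vector")
  model$w
}

#' Geometric margin width of a trained SVM
#'
#' The distance between the two supporting hyperplanes, `2 / ||w||_2`, where
#' `w` is the [decision_boundary()] vector. This is the quantity the
#' embedded feature-selection fitness maximizes.
#'
#' @param model A `"linear_svm"`.
#' @return Positive scalar.
#' @export
margin_width <- function(model) {
  if (!inherits(model, "linear_svm")) {
    stop("margin_width() requires a trained linear_svm", call. = FALSE)
  }
  if (model$degenerate) {
    stop("degenerate model: zero weight vector has no margin", call. = FALSE)
  }
  2 / model$w_norm
}

#' @rdname train_linear_svm
#' @param object A `"linear_svm"`.
#' @param newdata Numeric matrix over the same features the model was
#'   trained on.
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$w)) {
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), length(object$w)), call. = FALSE)
  }
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  dec <- drop(Xs %*% object$w) + object$bias
  pm1_to_coding(ifelse(dec >= 0, 1, -1), object$label_coding)
}

#' Classification accuracy
#'
#' @param predicted,actual Label vectors of equal length (any common coding).
#' @return Fraction of agreeing entries, in `[0, 1]`.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  mean(as.numeric(predicted) == as.numeric(actual))
}
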