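#' Mutual information between a feature and a binary label
#'
#' Plug-in estimate of \eqn{I(X;Y) = \sum p(x,y)\log_2 \frac{p(x,y)}{p(x)p(y)}}
#' in bits. Continuous features are discretized by equal-frequency binning
#' (quantile breaks); features with fewer distinct values than bins collapse
#' to their natural support, so binary or constant features are handled
#' exactly. A constant feature carries no information and returns 0.
#'
#' @param feature Numeric vector.
#' @param labels Binary label vector of equal length; both classes required.
#' @param n_bins Number of equal-frequency bins (>= 2).
#' @return Mutual information in bits, `0 <= MI <= H(labels)`.
#' @export
mutual_information <- function(feature, labels, n_bins = 8) {
  if (length(feature) != length(labels)) {
    stop("feature and labels must have equal length", call. = FALSE)
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  if (anyNA(feature) || anyNA(labels)) stop("missing values", call. = FALSE)
  y <- labels_to_pm1(labels)  # errors on single-class input
  if (length(unique(feature)) < 2L) return(0)
  bins <- discretize_ef(feature, n_bins)
  joint <- table(bins, y) / length(y)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# Equal-frequency binning; duplicate quantiles (heavily tied features)
# collapse to fewer bins.
discretize_ef <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 3L) return(factor(x)) # <= 2 distinct cut points: use support
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Rank features by mutual information with the label
#'
#' The filter benchmark's relevance metric: each feature's MI with the
#' outcome, ranked from weak to strong. Ties are broken by ascending feature
#' index, so the ranking is deterministic. Rankings should be computed on
#' the training split only; see [sequential_elimination_sweep()].
#'
#' @param X Feature matrix (training rows only).
#' @param y Binary labels.
#' @param n_bins Bins for [mutual_information()].
#' @return An object of class `"relevance_ranking"`: list with `mi`
#'   (per-feature MI, bits) and `order` (feature indices, weakest first).
#' @export
rank_features <- function(X, y, n_bins = 8) {
  X <- as.matrix(X)
  mi <- vapply(seq_len(ncol(X)), function(j) {
    mutual_information(X[, j], y, n_bins = n_bins)
  }, numeric(1))
  names(mi) <- colnames(X)
  structure(list(mi = mi, order = order(mi, seq_along(mi))),
            class = "relevance_ranking")
}

#' @export
print.relevance_ranking <- function(x, ...) {
  cat(sprintf("relevance_ranking over %d features; MI range [%.4g, %.4g] bits\n",
              length(x$mi), min(x$mi), max(x$mi)))
  invisible(x)
}

#' Select features whose relevance meets a threshold
#'
#' @param ranking A [rank_features()] result.
#' @param threshold Relevance threshold in bits (>= 0).
#' @return Logical inclusion mask over all features (possibly all-`FALSE`;
#'   callers must handle an empty selection).
#' @export
select_by_threshold <- function(ranking, threshold) {
  stopifnot(inherits(ranking, "relevance_ranking"))
  threshold <- check_real(threshold, "threshold", lower = 0)
  ranking$mi >= threshold
}

#' Sequential-elimination performance sweep
#'
#' The filter benchmark's evaluation protocol: rank features by MI on the
#' training split, then repeatedly delete the weakest features and retrain
#' the chosen benchmark classifier, recording training, testing, and overall
#' accuracy at each retained dimensionality `m = d, d - step, ..., 1`.
#' Overall accuracy is computed over the union of the training and testing
#' samples. Test rows never enter the ranking or the training.
#'
#' @param split A [stratified_split()] result.
#' @param spec A [benchmark_spec()].
#' @param step Number of weakest features deleted per sweep point.
#' @param n_bins Bins for the MI estimator.
#' @return An object of class `"sweep_curve"`: data frame with columns
#'   `m`, `train_acc`, `test_acc`, `overall_acc`; attribute `classifier`.
#' @export
sequential_elimination_sweep <- function(split, spec, step = 1, n_bins = 8) {
  stopifnot(inherits(split, "split_dataset"))
  step <- check_count(step, "step")
  X <- split$data$X; y <- split$data$y
  tr <- split$train; te <- split$test
  ranking <- rank_features(X[tr, , drop = FALSE], y[tr], n_bins = n_bins)
  strongest_first <- rev(ranking$order)
  d <- ncol(X)
  ms <- unique(c(seq(d, 1L, by = -step), 1L))
  rows <- lapply(ms, function(m) {
    keep <- strongest_first[seq_len(m)]
    rec <- tryCatch({
      clf <- train_benchmark_classifier(spec, X[tr, keep, drop = FALSE], y[tr])
      pred_tr <- predict(clf, X[tr, keep, drop = FALSE])
      pred_te <- predict(clf, X[te, keep, drop = FALSE])
      data.frame(m = m,
                 train_acc = accuracy(pred_tr, y[tr]),
                 test_acc = accuracy(pred_te, y[te]),
                 overall_acc = (sum(pred_tr == y[tr]) + sum(pred_te == y[te])) /
                   length(y))
    }, error = function(e) {
      warning(sprintf("sweep point m = %d failed: %s", m, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    rec
  })
  curve <- do.call(rbind, rows)
  structure(curve, class = c("sweep_curve", "data.frame"),
            classifier = spec$kind, ranking = ranking)
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("sweep_curve (%s): %d points, m in [%d, %d]\n",
              attr(x, "classifier"), nrow(x), min(x$m), max(x$m)))
  cat(sprintf("  best test accuracy %.3f at m = %d\n",
              max(x$test_acc), x$m[which.max(x$test_acc)]))
  invisible(x)
}
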