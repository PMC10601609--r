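#' Configuration for the synthetic cohort generator
#'
#' Describes a two-class Gaussian cohort with a planted block of informative
#' features among class-independent nuisance features. The defaults reproduce
#' the shape of the clinical study the package targets: 56 neonates, a
#' 248-dimensional wavelet-feature vector per neonate, and 32 positive
#' outcomes.
#'
#' Informative features receive a class-conditional mean shift of
#' `effect_size * noise_sd`, with the sign of the shift alternating across
#' the informative block (+, -, +, ...). With `correlation > 0` the block is
#' equicorrelated within class, so individual informative features can be
#' marginally weak while a contrast of two of them carries a strong joint
#' signal -- the combinatorial structure that filter-style selectors miss.
#'
#' @param n_samples Number of samples (rows).
#' @param n_features Number of features (columns).
#' @param n_positive Number of positive-class samples (label 1).
#' @param n_informative Number of planted informative features.
#' @param effect_size Class-mean separation on each informative feature, in
#'   units of the within-class standard deviation. Non-negative.
#' @param noise_sd Within-class standard deviation of every feature. Positive.
#' @param correlation Pairwise equicorrelation among informative features,
#'   in `[0, 1)`. Nuisance features are always i.i.d.
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   configuration, including the seed.
#' @return An object of class `"cohort_config"`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_samples = 56, n_features = 248, n_positive = 32,
                          n_informative = 10, effect_size = 1, noise_sd = 1,
                          correlation = 0, seed = 1) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", min = 2L),
    n_features = check_count(n_features, "n_features"),
    n_positive = check_count(n_positive, "n_positive"),
    n_informative = check_count(n_informative, "n_informative", min = 0L),
    effect_size = check_real(effect_size, "effect_size", lower = 0),
    noise_sd = check_real(noise_sd, "noise_sd", lower = 0, lower_open = TRUE),
    correlation = check_real(correlation, "correlation", lower = 0, upper = 1,
                             upper_open = TRUE),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (cfg$n_positive >= cfg$n_samples) {
    stop_config("n_positive", "must leave at least one negative sample")
  }
  if (cfg$n_informative > cfg$n_features) {
    stop_config("n_informative", "must not exceed n_features")
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic two-class cohort
#'
#' Draws a class-conditional Gaussian feature matrix according to a
#' [cohort_config()]: nuisance features are i.i.d. `N(0, noise_sd^2)` in both
#' classes; informative features are shifted between classes by
#' `effect_size * noise_sd` (alternating sign across the block) and,
#' optionally, equicorrelated within class. The indices of the planted
#' informative features are recorded so selection methods can be scored
#' against ground truth.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"feature_dataset"`: a list with elements
#'   `X` (numeric matrix, samples x features, with column names), `y`
#'   (integer labels, positive = 1, negative = 0), `feature_names`, and
#'   `informative` (integer indices of the planted features; empty for
#'   external data).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_features = 20, seed = 7))
#' dim(cohort$X)
#' table(cohort$y)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_samples
  d <- config$n_features
  k <- config$n_informative
  with_seed(config$seed, {
    y <- c(rep(1L, config$n_positive), rep(0L, n - config$n_positive))
    X <- matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
    informative <- if (k > 0) sort(sample.int(d, k)) else integer(0)
    if (k > 0) {
      rho <- config$correlation
      if (rho > 0) {
        # Equicorrelated block via a shared within-class latent factor.
        z <- stats::rnorm(n, sd = config$noise_sd)
        X[, informative] <- sqrt(rho) * z +
          sqrt(1 - rho) * X[, informative, drop = FALSE]
      }
      shift_sign <- rep_len(c(1, -1), k)
      delta <- config$effect_size * config$noise_sd
      X[y == 1L, informative] <- X[y == 1L, informative, drop = FALSE] +
        matrix(shift_sign * delta, sum(y == 1L), k, byrow = TRUE)
    }
    feature_names <- sprintf("f%0*d", nchar(d), seq_len(d))
    colnames(X) <- feature_names
    feature_dataset(X, y, informative = informative)
  })
}

#' Construct a feature dataset
#'
#' Bundles a numeric feature matrix with binary outcome labels. This is the
#' container every selection and classification function in the package
#' consumes.
#'
#' @param X Numeric matrix, samples x features, no missing values. Column
#'   names are used as feature names; unnamed columns are named `f1, f2, ...`.
#' @param y Binary labels, coded `{0, 1}` (positive = 1); both classes must
#'   be present.
#' @param informative Optional integer indices of known informative features
#'   (available for synthetic cohorts only).
#' @return An object of class `"feature_dataset"`.
#' @export
feature_dataset <- function(X, y, informative = integer(0)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature matrix contains missing values", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) {
    stop("labels must be coded {0,1}", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; both classes are required", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) {
    dup <- colnames(X)[duplicated(colnames(X))][1L]
    stop(sprintf("duplicate feature name: '%s'", dup), call. = FALSE)
  }
  informative <- as.integer(informative)
  if (length(informative) && (min(informative) < 1L || max(informative) > ncol(X))) {
    stop("informative indices out of range", call. = FALSE)
  }
  structure(
    list(X = X, y = y, feature_names = colnames(X), informative = informative),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature_dataset: %d samples x %d features (%d positive, %d negative)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1L), sum(x$y == 0L)))
  if (length(x$informative)) {
    cat(sprintf("  planted informative features: %d\n", length(x$informative)))
  }
  invisible(x)
}

#' Stratified train/test split
#'
#' Randomly assigns a fixed number of samples per class to the training
#' split; all remaining samples form the test split. The default counts --
#' 23 positive and 15 negative training samples -- give the 38/18 partition
#' used throughout the package's reference experiment design (test split
#' 9 positive, 9 negative on the default 56-sample cohort).
#'
#' @param dataset A [feature_dataset()].
#' @param train_counts Named vector `c(pos = ..., neg = ...)` of per-class
#'   training-set sizes.
#' @param seed Integer seed; the split is a pure function of it.
#' @return An object of class `"split_dataset"`: list with elements `data`
#'   (the parent dataset), `train` and `test` (integer row indices).
#' @export
stratified_split <- function(dataset, train_counts = c(pos = 23, neg = 15),
                             seed = 1) {
  stopifnot(inherits(dataset, "feature_dataset"))
  n_pos <- check_count(train_counts[["pos"]], "train_counts['pos']")
  n_neg <- check_count(train_counts[["neg"]], "train_counts['neg']")
  pos <- which(dataset$y == 1L)
  neg <- which(dataset$y == 0L)
  if (n_pos > length(pos)) {
    stop_config("train_counts['pos']",
                sprintf("requests %d of %d positive samples", n_pos, length(pos)))
  }
  if (n_neg > length(neg)) {
    stop_config("train_counts['neg']",
                sprintf("requests %d of %d negative samples", n_neg, length(neg)))
  }
  if (n_pos == length(pos) && n_neg == length(neg)) {
    stop("split leaves an empty test set", call. = FALSE)
  }
  with_seed(seed, {
    train <- sort(c(sample(pos, n_pos), sample(neg, n_neg)))
  })
  test <- setdiff(seq_along(dataset$y), train)
  for (part in list(train = train, test = test)) {
    if (length(unique(dataset$y[part])) < 2L) {
      stop("each split must contain both classes", call. = FALSE)
    }
  }
  structure(list(data = dataset, train = train, test = as.integer(test)),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  ytr <- x$data$y[x$train]; yte <- x$data$y[x$test]
  cat(sprintf("split_dataset: train %d (p = %d, n = %d), test %d (p = %d, n = %d)\n",
              length(x$train), sum(ytr == 1L), sum(ytr == 0L),
              length(x$test), sum(yte == 1L), sum(yte == 0L)))
  invisible(x)
}
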