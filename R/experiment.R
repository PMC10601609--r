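#' Configuration of an end-to-end experiment
#'
#' Bundles the stage configurations of a full experiment: synthetic cohort
#' generation, stratified splitting, the MI-filter benchmark sweep, and the
#' embedded GA run. Either stage (`filter`, `ga`) may be `NULL` to skip it.
#' All randomness flows from the named seeds inside the sub-configurations;
#' there is no global RNG dependence, so re-running a stored configuration
#' reproduces every artifact byte for byte.
#'
#' @param generator A [cohort_config()].
#' @param split List with `train_counts` (named `pos`/`neg` counts) and
#'   `seed`.
#' @param ga A [ga_config()], or `NULL` to skip the GA stage.
#' @param filter List with `classifiers` (subset of `simple_tree`,
#'   `rbf_svm`, `linear_svm`, `knn`), `n_bins`, `step`; or `NULL` to skip.
#' @param output_dir Directory for artifacts (created if absent).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(generator = cohort_config(),
                              split = list(train_counts = c(pos = 23, neg = 15),
                                           seed = 1),
                              ga = ga_config(),
                              filter = list(classifiers = c("simple_tree",
                                                            "rbf_svm",
                                                            "linear_svm",
                                                            "knn"),
                                            n_bins = 8, step = 1),
                              output_dir = tempfile("svmga-experiment-")) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (!inherits(generator, "cohort_config")) {
    generator <- tryCatch(do.call(cohort_config, as.list(generator)),
                          error = function(e) { note(conditionMessage(e)); NULL })
  }
  if (!is.list(split) || is.null(split$train_counts) || is.null(split$seed)) {
    note("split must be a list with 'train_counts' and 'seed'")
  }
  if (!is.null(ga) && !inherits(ga, "ga_config")) {
    ga <- tryCatch(do.call(ga_config, as.list(ga)),
                   error = function(e) { note(conditionMessage(e)); NULL })
  }
  if (!is.null(filter)) {
    bad <- setdiff(filter$classifiers,
                   c("simple_tree", "rbf_svm", "linear_svm", "knn"))
    if (length(bad)) note(sprintf("unknown filter classifier(s): %s",
                                  paste(bad, collapse = ", ")))
    if (is.null(filter$n_bins)) filter$n_bins <- 8
    if (is.null(filter$step)) filter$step <- 1
  }
  if (length(problems)) {
    stop(paste(c("invalid experiment configuration:", problems),
               collapse = "\n  "), call. = FALSE)
  }
  structure(list(generator = generator, split = split, ga = ga,
                 filter = filter, output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Accepts a document with top-level keys `generator`, `split`, `ga`,
#' `filter`, `output_dir`, each holding the fields of the corresponding
#' constructor. Missing keys take the package defaults; `ga: null` or
#' `filter: null` skip the stage.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(doc$generator)) args$generator <- doc$generator
  if ("ga" %in% names(doc)) {
    # args[name] <- list(...) keeps an explicit NULL (stage skipped)
    args["ga"] <- list(doc$ga)
  }
  if ("filter" %in% names(doc)) {
    f <- doc$filter
    if (!is.null(f)) f$classifiers <- unlist(f$classifiers)
    args["filter"] <- list(f)
  }
  if (!is.null(doc$split)) {
    tc <- unlist(doc$split$train_counts)
    args$split <- list(train_counts = c(pos = as.integer(tc[["pos"]]),
                                        neg = as.integer(tc[["neg"]])),
                       seed = as.integer(doc$split$seed %||% 1L))
  }
  if (!is.null(doc$output_dir)) args$output_dir <- doc$output_dir
  do.call(experiment_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-precision CSV writer so identical runs give byte-identical files.
write_csv_stable <- function(df, path) {
  cells <- vapply(df, function(col) {
    if (is.double(col)) sprintf("%.10g", col) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  writeLines(c(paste(names(df), collapse = ","),
               apply(cells, 1L, paste, collapse = ",")), path)
  invisible(path)
}

#' Run an end-to-end experiment
#'
#' Generates the cohort, splits it, and executes the configured stages:
#' one [sequential_elimination_sweep()] per benchmark classifier (written
#' as `sweep_<kind>.csv`) and/or one [svmga()] fit (trajectory as
#' `trajectory.csv`, selected subset as `best_subset.json`). The cohort
#' itself (`cohort.csv` + metadata sidecar), the resolved configuration,
#' and a `summary.json` are always written, so every reported number can
#' be recomputed from the artifact directory alone.
#'
#' @param config An [experiment_config()].
#' @return An object of class `"experiment_report"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  cohort <- generate_cohort(config$generator)
  write_dataset(cohort, out("cohort.csv"))
  split <- stratified_split(cohort, train_counts = config$split$train_counts,
                            seed = config$split$seed)

  sweep_files <- character(0)
  if (!is.null(config$filter)) {
    for (kind in config$filter$classifiers) {
      curve <- sequential_elimination_sweep(
        split, benchmark_spec(kind), step = config$filter$step,
        n_bins = config$filter$n_bins)
      f <- out(sprintf("sweep_%s.csv", kind))
      write_csv_stable(cbind(curve, classifier = kind), f)
      sweep_files <- c(sweep_files, f)
    }
  }

  fit <- NULL
  trajectory_file <- NULL
  if (!is.null(config$ga)) {
    fit <- svmga(split, config = config$ga)
    trajectory_file <- out("trajectory.csv")
    write_csv_stable(fit$trajectory, trajectory_file)
    jsonlite::write_json(
      list(mask = fit$best_mask,
           features = fit$features,
           m = fit$m, d = fit$d,
           fitness = fit$fitness[c("ff1", "ff2", "ff3", "ff_total",
                                   "acc_train", "m", "margin")]),
      out("best_subset.json"), auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    version = as.character(utils::packageVersion("svmga")),
    seeds = list(generator = config$generator$seed,
                 split = config$split$seed,
                 ga = if (!is.null(config$ga)) config$ga$seed),
    d = config$generator$n_features,
    m_best = if (!is.null(fit)) fit$m,
    accuracies = if (!is.null(fit)) as.list(fit$accuracies),
    convergence_epoch = if (!is.null(fit)) {
      unname(summary(fit)$convergence_epoch)
    },
    epochs_run = if (!is.null(fit)) nrow(fit$trajectory),
    config = unclass_config(config)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(list(summary = summary, fit = fit,
                 cohort_file = out("cohort.csv"),
                 sweep_files = sweep_files,
                 trajectory_file = trajectory_file,
                 output_dir = config$output_dir),
            class = "experiment_report")
}

unclass_config <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_config) else x
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(summarize_experiment(x), sep = "\n")
  invisible(x)
}

#' Human-readable summary of an experiment report
#'
#' @param report An [run_experiment()] result.
#' @return Character vector of summary lines, invisibly printed by
#'   [print.experiment_report()].
#' @export
summarize_experiment <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  s <- report$summary
  lines <- c(sprintf("experiment artifacts in %s", report$output_dir))
  if (!is.null(s$m_best)) {
    lines <- c(lines,
      sprintf("dimensionality reduced %d -> %d", s$d, s$m_best),
      sprintf("final accuracy: train %.3f, test %.3f, overall %.3f",
              s$accuracies$train, s$accuracies$test, s$accuracies$overall),
      sprintf("best fitness first reached at epoch %d (of %d run)",
              s$convergence_epoch, s$epochs_run))
  } else {
    lines <- c(lines, "no GA stage run")
  }
  if (length(report$sweep_files)) {
    lines <- c(lines, sprintf("filter sweeps: %s",
                              paste(basename(report$sweep_files),
                                    collapse = ", ")))
  }
  lines
}
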