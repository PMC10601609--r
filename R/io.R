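#' Write a feature dataset to delimited text
#'
#' Writes the feature matrix and label column as a headed CSV, one sample
#' per row, with the label column named `pvl` by default. Values are written
#' with 17 significant digits so a write/read round trip reproduces every
#' double exactly. When the dataset records planted informative features, a
#' sidecar JSON file (`<path>.json`) stores them alongside the feature names.
#'
#' @param dataset A [feature_dataset()].
#' @param path Output CSV path.
#' @param label_column Name of the label column.
#' @return `path`, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path, label_column = "pvl") {
  stopifnot(inherits(dataset, "feature_dataset"))
  if (label_column %in% dataset$feature_names) {
    stop(sprintf("label column '%s' collides with a feature name", label_column),
         call. = FALSE)
  }
  # %.17g is the shortest representation guaranteed to round-trip a double.
  cells <- matrix(sprintf("%.17g", dataset$X), nrow(dataset$X))
  lines <- c(
    paste(c(dataset$feature_names, label_column), collapse = ","),
    paste(apply(cells, 1L, paste, collapse = ","), dataset$y, sep = ",")
  )
  writeLines(lines, path)
  if (length(dataset$informative)) {
    jsonlite::write_json(
      list(informative = dataset$informative,
           feature_names = dataset$feature_names),
      paste0(path, ".json"),
      auto_unbox = FALSE, digits = NA
    )
  }
  invisible(path)
}

#' Read a feature dataset from delimited text
#'
#' Expects a headed CSV with numeric feature columns and one binary label
#' column. If a sidecar metadata file `<path>.json` exists, the planted
#' informative-feature indices stored there are restored.
#'
#' @param path CSV path.
#' @param label_column Name of the label column (default `"pvl"`).
#' @return A [feature_dataset()].
#' @export
read_dataset <- function(path, label_column = "pvl") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop(sprintf("duplicate feature name: '%s' (column %d)",
                 names(df)[duplicated(names(df))][1L],
                 which(duplicated(names(df)))[1L]), call. = FALSE)
  }
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  if (sum(names(df) == label_column) > 1L) {
    stop(sprintf("multiple columns named '%s'", label_column), call. = FALSE)
  }
  y_raw <- df[[label_column]]
  feat <- df[names(df) != label_column]
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      stop(sprintf("feature column '%s' is not numeric", names(feat)[j]),
           call. = FALSE)
    }
    if (anyNA(feat[[j]])) {
      stop(sprintf("missing value in column '%s', row %d",
                   names(feat)[j], which(is.na(feat[[j]]))[1L]), call. = FALSE)
    }
  }
  uy <- sort(unique(y_raw))
  if (anyNA(y_raw) || length(uy) != 2L || !all(uy %in% c(0, 1))) {
    stop(sprintf("label column '%s' must contain exactly the values 0 and 1 (found: %s)",
                 label_column, paste(utils::head(uy, 5L), collapse = ", ")),
         call. = FALSE)
  }
  informative <- integer(0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$informative)) informative <- as.integer(meta$informative)
  }
  feature_dataset(as.matrix(feat), as.integer(y_raw), informative = informative)
}
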