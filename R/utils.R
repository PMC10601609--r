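# Internal helpers shared across the package.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so exported functions are pure in their seed argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_count <- function(value, field, min = 1L) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      value != as.integer(value) || value < min) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(value)
}

check_real <- function(value, field, lower = -Inf, upper = Inf,
                       lower_open = FALSE, upper_open = FALSE) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value)) {
    stop_config(field, "must be a single finite number")
  }
  lo_ok <- if (lower_open) value > lower else value >= lower
  hi_ok <- if (upper_open) value < upper else value <= upper
  if (!lo_ok || !hi_ok) {
    stop_config(field, sprintf("must lie in %s%g, %g%s",
                               if (lower_open) "(" else "[", lower, upper,
                               if (upper_open) ")" else "]"))
  }
  as.numeric(value)
}

# Binary labels in any of the accepted codings -> internal {-1, +1}.
labels_to_pm1 <- function(y) {
  v <- if (is.factor(y)) as.numeric(as.character(y)) else as.numeric(y)
  u <- sort(unique(v))
  if (identical(u, c(0, 1))) return(ifelse(v > 0, 1, -1))
  if (identical(u, c(-1, 1))) return(v)
  if (identical(u, 0) || identical(u, 1) || identical(u, -1)) {
    stop("labels contain a single class; both classes are required", call. = FALSE)
  }
  stop("labels must be binary, coded {0,1} or {-1,+1}", call. = FALSE)
}

# Remember which coding the caller used so predictions come back in kind.
label_coding <- function(y) {
  v <- if (is.factor(y)) as.numeric(as.character(y)) else as.numeric(y)
  if (any(v < 0)) "pm1" else "01"
}

pm1_to_coding <- function(y_pm1, coding) {
  if (coding == "01") ifelse(y_pm1 > 0, 1, 0) else y_pm1
}
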