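# Internal validation helpers. All user-facing domain errors are signalled
# with class "ppvplan_validation_error" so the CLI can map them to a
# dedicated exit code; the condition message always names the offending field.

abort_validation <- function(field, msg) {
  stop(structure(
    class = c("ppvplan_validation_error", "error", "condition"),
    list(message = sprintf("invalid `%s`: %s", field, msg), call = sys.call(-1),
         field = field)
  ))
}

check_prob <- function(x, field, lower = 0, upper = 1,
                       open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(field, "must be a single non-missing number")
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_validation(field, sprintf(
      "must lie in %s%s, %s%s (got %g)",
      if (open_lower) "(" else "[", lower, upper,
      if (open_upper) ")" else "]", x
    ))
  }
  x
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_validation(field, "must be TRUE or FALSE")
  }
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != as.integer(x) || x < min) {
    abort_validation(field, sprintf("must be an integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(field, "must be a single finite number")
  }
  x
}

check_prob_vector <- function(x, field, lower = 0, upper = 1,
                              open_lower = FALSE, open_upper = FALSE) {
  if (length(x) == 0L) abort_validation(field, "must not be empty")
  for (xi in x) check_prob(xi, field, lower, upper, open_lower, open_upper)
  as.numeric(x)
}
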