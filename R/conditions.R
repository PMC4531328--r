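# Condition classes shared across the package. Validation errors (bad domain,
# bad schema) and numerical failures (non-convergence) are distinguishable so
# callers -- in particular the CLI -- can map them to distinct exit codes.

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("rbelet_validation_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_numerical <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("rbelet_numerical_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_validation(sprintf("'%s' must be > 0 (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    stop_validation(sprintf("'%s' must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop_validation(sprintf("'%s' must be a non-empty finite numeric vector", name))
  }
  if (nonneg && any(x < 0)) {
    stop_validation(sprintf("'%s' must be non-negative", name))
  }
  invisible(x)
}
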