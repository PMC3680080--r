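# Internal validation helpers shared across modules.

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "stepminer2d_invalid_input", ...)
}

abort_degenerate <- function(msg, ...) {
  rlang::abort(msg, class = "stepminer2d_degenerate_input", ...)
}

check_numeric_vector <- function(x, arg, min_len = 1L, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort_invalid(sprintf("`%s` must be numeric, not %s.", arg, class(x)[1]))
  }
  if (!allow_na && anyNA(x)) {
    abort_invalid(sprintf("`%s` must not contain missing values.", arg))
  }
  if (!allow_na && any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must contain only finite values.", arg))
  }
  if (length(x) < min_len) {
    abort_invalid(sprintf(
      "`%s` must have at least %d observations, got %d.",
      arg, min_len, length(x)
    ))
  }
  invisible(x)
}

check_scalar_in <- function(x, arg, lower, upper, closed = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    if (closed) (x >= lower && x <= upper) else (x > lower && x < upper)
  if (!ok) {
    abort_invalid(sprintf(
      "`%s` must be a single number in %s%g, %g%s.",
      arg, if (closed) "[" else "(", lower, upper, if (closed) "]" else ")"
    ))
  }
  invisible(x)
}

check_matrix <- function(x, arg) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_invalid(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort_invalid(sprintf(
      "`%s` must have row names (feature ids) and column names (sample ids).",
      arg
    ))
  }
  invisible(x)
}

# Argmax with the package-wide tie-break: highest snr, then largest signal,
# then smallest index. +Inf snr sorts above every finite value.
select_best_split <- function(snr, signal) {
  ord <- order(-snr, -signal, seq_along(snr))
  ord[1]
}
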