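#' Fit a two-level step function to one variable by SNR maximization
#'
#' Sorts the observations in ascending order and fits a step function
#' `f(i) = mu1` for `i <= t` and `f(i) = mu2` for `i > t`, choosing the split
#' `t` that maximizes the signal-to-noise ratio
#' `SNR(t) = sum((f - mean(x))^2) / sum((f - x_sorted)^2)`. The dichotomization
#' threshold is the midpoint of the two order statistics straddling the
#' optimal split, `(x_(t*) + x_(t*+1)) / 2`.
#'
#' The optimal SNR reflects the marginal distribution of the data: it is 3 in
#' the large-sample limit for uniform data, approximately 1.75 for Gaussian
#' data (whatever the mean and variance), and grows without bound for a sharp
#' two-mode mixture. A large SNR therefore signals bimodality, i.e. that an
#' on/off reading of the variable is meaningful.
#'
#' When several splits achieve the same SNR (including a perfect fit with
#' zero noise, reported as `snr = Inf`), the split with the larger signal
#' wins, then the smaller `t`.
#'
#' @param x Numeric vector of at least 2 finite observations, no missing
#'   values (remove them upstream).
#' @return An object of class `step_fit_1d` with fields `split_index` (the
#'   number of observations in the lower segment), `mu1`, `mu2` (segment
#'   means, `mu1 <= mu2`), `signal`, `noise`, `snr`, `threshold` (data-scale
#'   dichotomization cutoff) and `n`. Use [generics::tidy()] /
#'   [generics::glance()] for a one-row tibble and [ggplot2::autoplot()] for
#'   the fitted step.
#' @examples
#' fit <- fit_step_1d(c(0.1, 0.2, 0.15, 0.9, 0.85, 0.3, 0.8, 0.88))
#' fit$threshold
#' dichotomize(c(0.05, 0.95), fit$threshold)
#' @seealso [snr_profile_1d()] for the full SNR-vs-split curve,
#'   [stepminer2d()] for the bivariate extension.
#' @export
fit_step_1d <- function(x) {
  check_numeric_vector(x, "x", min_len = 2L)
  xs <- sort(x, method = "radix")
  n <- length(xs)
  prof <- snr_components(xs)
  if (all(prof$signal == 0)) {
    abort_degenerate(
      "All observations are identical; no dichotomization threshold exists."
    )
  }
  best <- select_best_split(prof$snr, prof$signal)
  structure(
    list(
      split_index = best,
      mu1 = prof$mu1[best],
      mu2 = prof$mu2[best],
      signal = prof$signal[best],
      noise = prof$noise[best],
      snr = prof$snr[best],
      threshold = (xs[best] + xs[best + 1]) / 2,
      n = n,
      sorted_values = xs
    ),
    class = "step_fit_1d"
  )
}

# SNR(t) for every split of the *sorted* vector, from prefix sums: O(n).
snr_components <- function(xs) {
  n <- length(xs)
  cs <- cumsum(xs)
  cq <- cumsum(xs^2)
  t <- seq_len(n - 1L)
  mu1 <- cs[t] / t
  mu2 <- (cs[n] - cs[t]) / (n - t)
  mu <- cs[n] / n
  signal <- t * (mu1 - mu)^2 + (n - t) * (mu2 - mu)^2
  noise <- pmax(0, cq[t] - cs[t]^2 / t) +
    pmax(0, (cq[n] - cq[t]) - (cs[n] - cs[t])^2 / (n - t))
  # a perfect two-level fit leaves noise at rounding level, not exactly 0
  noise[noise <= 1e-9 * max(signal + noise)] <- 0
  snr <- ifelse(noise == 0, Inf, signal / noise)
  list(t = t, mu1 = mu1, mu2 = mu2, signal = signal, noise = noise, snr = snr)
}

#' SNR profile over every candidate split
#'
#' Diagnostic view of the exhaustive search done by [fit_step_1d()]: the
#' signal, noise and SNR for each split `t = 1, ..., n-1` of the sorted data.
#'
#' @inheritParams fit_step_1d
#' @return A tibble with columns `t`, `mu1`, `mu2`, `signal`, `noise`, `snr`;
#'   its maximum `snr` equals `fit_step_1d(x)$snr`.
#' @export
snr_profile_1d <- function(x) {
  check_numeric_vector(x, "x", min_len = 2L)
  if (length(unique(x)) == 1L) {
    abort_degenerate(
      "All observations are identical; no dichotomization threshold exists."
    )
  }
  xs <- sort(x, method = "radix")
  tibble::as_tibble(snr_components(xs))
}

#' Dichotomize a continuous variable at a threshold
#'
#' Converts continuous measurements into binary on/off calls: `"high"` when
#' the value exceeds the threshold, `"low"` when it is less than or equal to
#' it (the midpoint-threshold convention: values tied with the threshold are
#' low). Missing values stay missing.
#'
#' @param x Numeric vector (missing values allowed, propagated).
#' @param threshold Single finite number, typically `fit_step_1d(x)$threshold`
#'   or a threshold from [stepminer2d()].
#' @return A factor with levels `c("low", "high")`, same length as `x`.
#' @export
dichotomize <- function(x, threshold) {
  if (!is.numeric(x)) abort_invalid("`x` must be numeric.")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold)) {
    abort_invalid("`threshold` must be a single finite number.")
  }
  factor(
    ifelse(x > threshold, "high", "low"),
    levels = c("low", "high")
  )
}

#' @export
print.step_fit_1d <- function(x, ...) {
  cat("StepMiner 1D fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf(
    "  split %d | mu1 = %.4g, mu2 = %.4g | threshold = %.4g | SNR = %.4g\n",
    x$split_index, x$mu1, x$mu2, x$threshold, x$snr
  ))
  invisible(x)
}

#' @method tidy step_fit_1d
#' @export
tidy.step_fit_1d <- function(x, ...) {
  tibble::tibble(
    split_index = x$split_index,
    mu1 = x$mu1,
    mu2 = x$mu2,
    threshold = x$threshold,
    signal = x$signal,
    noise = x$noise,
    snr = x$snr
  )
}

#' @method glance step_fit_1d
#' @export
glance.step_fit_1d <- function(x, ...) {
  tibble::tibble(n = x$n, snr = x$snr, threshold = x$threshold)
}

#' @method autoplot step_fit_1d
#' @export
autoplot.step_fit_1d <- function(object, ...) {
  n <- object$n
  df <- tibble::tibble(
    i = seq_len(n),
    value = object$sorted_values,
    fitted = ifelse(seq_len(n) <= object$split_index, object$mu1, object$mu2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "rank", y = "value",
      title = sprintf("Step fit: SNR = %.3g, threshold = %.3g",
                      object$snr, object$threshold)
    )
}
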