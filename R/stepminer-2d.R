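#' Construct a paired series from two jointly measured variables
#'
#' Pairs one gene's (log-scale) expression with the beta values of one of its
#' CpG sites, sample by sample. Samples missing either measurement are
#' dropped; at least 4 complete pairs must remain.
#'
#' @param x Numeric vector, the first variable (conventionally expression).
#' @param y Numeric vector, the second variable (conventionally methylation
#'   beta values), same length as `x`.
#' @param ids Optional character vector of sample labels; defaults to
#'   `"s1", "s2", ...`.
#' @return A tibble with columns `sample_id`, `x`, `y` and no missing values.
#' @export
paired_series <- function(x, y, ids = NULL) {
  if (!is.numeric(x) || !is.numeric(y)) {
    abort_invalid("`x` and `y` must be numeric vectors.")
  }
  if (length(x) != length(y)) {
    abort_invalid(sprintf(
      "`x` and `y` must have equal length (%d vs %d).", length(x), length(y)
    ))
  }
  if (is.null(ids)) ids <- paste0("s", seq_along(x))
  if (length(ids) != length(x)) {
    abort_invalid("`ids` must match the length of `x`.")
  }
  keep <- is.finite(x) & is.finite(y)
  out <- tibble::tibble(
    sample_id = as.character(ids)[keep],
    x = x[keep],
    y = y[keep]
  )
  if (nrow(out) < 4L) {
    abort_invalid(sprintf(
      "A paired series needs at least 4 complete pairs; %d remain.", nrow(out)
    ))
  }
  out
}

as_paired_series <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("x", "y") %in% names(pairs))) {
    abort_invalid("`pairs` must be a data frame with numeric columns `x` and `y`.")
  }
  ids <- if ("sample_id" %in% names(pairs)) pairs$sample_id else NULL
  paired_series(pairs$x, pairs$y, ids)
}

#' Rank-transform a paired series
#'
#' Replaces each variable by its rank among all observations of that
#' variable, so every sample maps to a point `(i, j)` on the `n x n` rank
#' lattice, each axis a permutation of `1..n`. Ties are broken by sample
#' order (stable first-occurrence ranks), which makes the mapping a
#' deterministic bijection as required by the surface construction.
#'
#' @param pairs A data frame with numeric columns `x` and `y` (see
#'   [paired_series()]).
#' @return The input as a tibble with integer columns `x_rank` and `y_rank`
#'   appended.
#' @export
rank_transform <- function(pairs) {
  pairs <- as_paired_series(pairs)
  dplyr::mutate(
    pairs,
    x_rank = rank(.data$x, ties.method = "first"),
    y_rank = rank(.data$y, ties.method = "first")
  )
}

#' Build the non-decreasing rank-space surface
#'
#' Each sample contributes a height `z = x_std + y_std` (both variables
#' standardized to zero mean and unit variance so they contribute equally) at
#' its rank point `(i, j)`. Rank points with no sample take the running
#' lower-left maximum `z(i,j) = max_{u<=i, v<=j} z(u,v)` (the global minimum
#' height where that prefix is empty), which makes the surface non-decreasing
#' along both axes. For efficiency the surface is approximated on a
#' `grid_size x grid_size` grid: each rank axis is cut into near-equal-count
#' bins, a cell takes the maximum height among samples mapped into it, and
#' the monotone fill is applied at bin resolution. This equals sampling the
#' exact full-resolution surface at the bin upper-edge ranks.
#'
#' @inheritParams rank_transform
#' @param grid_size Number of bins per axis (default 50). A warning is issued
#'   when there are fewer samples than grid cells per axis.
#' @return An object of class `sm_surface`: a list with `z` (a
#'   `grid_size x grid_size` matrix, rows = y bins, columns = x bins, origin
#'   at low/low), `x_bin_edges` / `y_bin_edges` (rank cutoffs, `grid_size+1`
#'   integers from 0 to n), `global_min`, `grid_size`, `n`.
#' @export
build_surface <- function(pairs, grid_size = 50) {
  pairs <- as_paired_series(pairs)
  if (!is.numeric(grid_size) || length(grid_size) != 1L || grid_size < 2 ||
      grid_size != round(grid_size)) {
    abort_invalid("`grid_size` must be a single integer >= 2.")
  }
  G <- as.integer(grid_size)
  n <- nrow(pairs)
  if (n < G) {
    rlang::warn(sprintf(
      "Fewer samples (%d) than grid bins (%d); several bins will be empty.",
      n, G
    ))
  }
  sdx <- stats::sd(pairs$x)
  sdy <- stats::sd(pairs$y)
  if (sdx == 0 || sdy == 0) {
    abort_degenerate("Zero variance in `x` or `y`; the surface is undefined.")
  }
  h <- (pairs$x - mean(pairs$x)) / sdx + (pairs$y - mean(pairs$y)) / sdy
  i <- rank(pairs$x, ties.method = "first")
  j <- rank(pairs$y, ties.method = "first")
  bi <- ceiling(i * G / n)
  bj <- ceiling(j * G / n)
  gmin <- min(h)

  raw <- tapply(h, list(factor(bj, 1:G), factor(bi, 1:G)), max)
  raw[is.na(raw)] <- gmin
  z <- matrix(gmin, G, G)
  prev <- rep(gmin, G)
  for (a in seq_len(G)) {
    z[, a] <- cummax(pmax(raw[, a], prev))
    prev <- z[, a]
  }
  structure(
    list(
      z = z,
      x_bin_edges = as.integer(floor((0:G) * n / G)),
      y_bin_edges = as.integer(floor((0:G) * n / G)),
      global_min = gmin,
      grid_size = G,
      n = n
    ),
    class = "sm_surface"
  )
}

#' Fit the six-parameter bivariate step function to a surface
#'
#' Exhaustively searches every grid split `(tx, ty)` for the four-block step
#' function `f(i,j) = mu11` (low/low), `mu12` (x high / y low), `mu21`
#' (x low / y high), `mu22` (high/high) that maximizes
#' `SNR = sum((f - mean(z))^2) / sum((f - z)^2)` over all grid cells. The
#' block means are the surface means over the four blocks, so the noise is
#' the total sum of squares minus the signal and maximizing SNR is
#' equivalent to maximizing the signal. Ties are broken by larger signal,
#' then smaller `tx`, then smaller `ty`; a perfect fit has `snr = Inf`.
#'
#' @param surface An [sm_surface][build_surface()] object.
#' @return An object of class `step_fit_2d` with grid splits `tx`, `ty`,
#'   block means `mu11`, `mu12`, `mu21`, `mu22`, `signal`, `noise`, `snr`,
#'   and (until mapped by [stepminer2d()]) `NA` data-scale thresholds.
#' @export
fit_step_2d <- function(surface) {
  if (!inherits(surface, "sm_surface")) {
    abort_invalid("`surface` must be built by `build_surface()`.")
  }
  z <- surface$z
  G <- surface$grid_size
  S <- t(apply(apply(z, 2, cumsum), 1, cumsum))   # S[b, a] = sum z[1:b, 1:a]
  tot <- S[G, G]
  tss <- sum(z^2) - tot^2 / G^2
  if (tss <= 0) {
    abort_degenerate("Constant surface; no split separates anything.")
  }
  g1 <- seq_len(G - 1L)
  s11 <- S[g1, g1, drop = FALSE]
  s12 <- matrix(S[g1, G], G - 1L, G - 1L) - s11          # i > tx, j <= ty
  s21 <- matrix(S[G, g1], G - 1L, G - 1L, byrow = TRUE) - s11
  s22 <- tot - s11 - s12 - s21
  n11 <- outer(g1, g1)                                    # rows ty, cols tx
  n12 <- outer(g1, G - g1)
  n21 <- outer(G - g1, g1)
  n22 <- outer(G - g1, G - g1)
  signal <- s11^2 / n11 + s12^2 / n12 + s21^2 / n21 + s22^2 / n22 -
    tot^2 / G^2
  noise <- tss - signal
  # a perfect four-block fit leaves noise at rounding level, not exactly 0
  noise[noise <= 1e-9 * tss] <- 0
  snr <- ifelse(noise == 0, Inf, signal / noise)
  # Matrices are indexed [ty, tx]; column-major linearization runs ty fastest
  # within each tx, i.e. candidates in (tx, ty)-lexicographic order, which is
  # exactly the tie-break precedence (smaller tx, then smaller ty).
  best <- select_best_split(as.vector(snr), as.vector(signal))
  tx <- ((best - 1L) %/% (G - 1L)) + 1L
  ty <- ((best - 1L) %% (G - 1L)) + 1L
  structure(
    list(
      tx = tx, ty = ty,
      mu11 = s11[ty, tx] / n11[ty, tx],
      mu12 = s12[ty, tx] / n12[ty, tx],
      mu21 = s21[ty, tx] / n21[ty, tx],
      mu22 = s22[ty, tx] / n22[ty, tx],
      signal = signal[ty, tx],
      noise = noise[ty, tx],
      snr = snr[ty, tx],
      grid_size = G,
      threshold_x = NA_real_,
      threshold_y = NA_real_,
      n = surface$n
    ),
    class = "step_fit_2d"
  )
}

#' Joint two-variable dichotomization (StepMiner2D)
#'
#' The full bivariate pipeline: rank-transform the pair, build the
#' non-decreasing surface over rank space ([build_surface()]), fit the
#' four-block step function by exhaustive SNR maximization
#' ([fit_step_2d()]), and map the winning grid splits back to data-scale
#' thresholds. The grid split `tx` corresponds to the rank cutoff at the
#' upper edge of bin `tx`; the threshold is the midpoint of the two order
#' statistics straddling that rank, exactly as in the univariate fit.
#' [dichotomize()] with these thresholds then gives the joint on/off calls.
#'
#' As in 1D, the optimal SNR measures multi-modality of the joint
#' distribution (about 3 for independent uniform pairs, about 1.75 for
#' independent Gaussian pairs, unbounded for sharp mode mixtures) -- not the
#' association between the variables, which is what the hypergeometric test
#' ([hypergeom_pvalue()]) is for.
#'
#' @inheritParams build_surface
#' @return A `step_fit_2d` object (see [fit_step_2d()]) whose `threshold_x`
#'   and `threshold_y` are on the original data scales, with the input pairs
#'   attached for plotting.
#' @examples
#' set.seed(1)
#' pairs <- paired_series(x = rnorm(200), y = runif(200))
#' fit <- stepminer2d(pairs, grid_size = 10)
#' tidy(fit)
#' @export
stepminer2d <- function(pairs, grid_size = 50) {
  pairs <- as_paired_series(pairs)
  surface <- build_surface(pairs, grid_size)
  fit <- fit_step_2d(surface)
  n <- nrow(pairs)
  fit$threshold_x <- rank_midpoint(pairs$x, surface$x_bin_edges[fit$tx + 1L], n)
  fit$threshold_y <- rank_midpoint(pairs$y, surface$y_bin_edges[fit$ty + 1L], n)
  fit$data <- pairs
  fit
}

# Midpoint of the order statistics straddling rank cutoff r (clamped to the
# valid 1..n-1 range, relevant only when bins outnumber samples).
rank_midpoint <- function(v, r, n) {
  r <- min(max(r, 1L), n - 1L)
  vs <- sort(v, method = "radix")
  (vs[r] + vs[r + 1L]) / 2
}

#' @export
print.step_fit_2d <- function(x, ...) {
  cat("StepMiner2D fit (n = ", x$n, ", grid ", x$grid_size, "x",
      x$grid_size, ")\n", sep = "")
  cat(sprintf("  splits (tx, ty) = (%d, %d) | SNR = %.4g\n",
              x$tx, x$ty, x$snr))
  cat(sprintf("  block means: ll %.3g, lr %.3g, ul %.3g, ur %.3g\n",
              x$mu11, x$mu12, x$mu21, x$mu22))
  cat(sprintf("  thresholds: x = %.4g, y = %.4g\n",
              x$threshold_x, x$threshold_y))
  invisible(x)
}

#' @method tidy step_fit_2d
#' @export
tidy.step_fit_2d <- function(x, ...) {
  tibble::tibble(
    tx = x$tx, ty = x$ty,
    mu11 = x$mu11, mu12 = x$mu12, mu21 = x$mu21, mu22 = x$mu22,
    threshold_x = x$threshold_x, threshold_y = x$threshold_y,
    signal = x$signal, noise = x$noise, snr = x$snr
  )
}

#' @method glance step_fit_2d
#' @export
glance.step_fit_2d <- function(x, ...) {
  tibble::tibble(
    n = x$n, grid_size = x$grid_size, snr = x$snr,
    threshold_x = x$threshold_x, threshold_y = x$threshold_y
  )
}

#' @method autoplot step_fit_2d
#' @export
autoplot.step_fit_2d <- function(object, ...) {
  if (is.null(object$data)) {
    abort_invalid("This fit carries no data; run `stepminer2d()` to plot.")
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = object$threshold_x,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(yintercept = object$threshold_y,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      title = sprintf("StepMiner2D: SNR = %.3g", object$snr),
      x = "x", y = "y"
    )
}

#' @method autoplot sm_surface
#' @export
autoplot.sm_surface <- function(object, ...) {
  G <- object$grid_size
  df <- tibble::tibble(
    x_bin = rep(seq_len(G), each = G),
    y_bin = rep(seq_len(G), times = G),
    z = as.vector(object$z)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_bin, .data$y_bin,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "x rank bin", y = "y rank bin", fill = "z")
}
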