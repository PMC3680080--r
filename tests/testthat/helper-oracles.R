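# Brute-force reference implementations, written directly from the
# definitions and kept independent of the package internals (no prefix sums,
# no shared code paths). Used to verify the optimized fitters.

# Evaluate every split of the sorted data from the definitional formulas.
oracle_profile_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  mu <- mean(xs)
  out <- data.frame(t = seq_len(n - 1), mu1 = NA_real_, mu2 = NA_real_,
                    signal = NA_real_, noise = NA_real_, snr = NA_real_)
  for (t in seq_len(n - 1)) {
    mu1 <- mean(xs[1:t])
    mu2 <- mean(xs[(t + 1):n])
    f <- c(rep(mu1, t), rep(mu2, n - t))
    signal <- sum((f - mu)^2)
    noise <- sum((f - xs)^2)
    out$mu1[t] <- mu1
    out$mu2[t] <- mu2
    out$signal[t] <- signal
    out$noise[t] <- noise
    # shared zero-noise convention: rounding-level residuals are a perfect fit
    out$snr[t] <- if (noise <= 1e-9 * sum((xs - mu)^2)) Inf else signal / noise
  }
  out
}

# Splits achieving the maximum SNR up to a small tolerance (near-ties can be
# resolved differently by mathematically equivalent float computations).
oracle_top_splits <- function(profile, tol = 1e-9) {
  top <- max(profile$snr)
  if (is.infinite(top)) {
    cand <- profile[is.infinite(profile$snr), , drop = FALSE]
    best_sig <- max(cand$signal)
    cand$t[cand$signal >= best_sig - tol * max(1, abs(best_sig))]
  } else {
    profile$t[profile$snr >= top - tol * max(1, top)]
  }
}

# Full n x n rank-resolution surface, computed point by point from the
# definition (occupied points carry their height; empty points take the max
# over all occupied points in their lower-left prefix, or the global minimum
# height when that prefix is empty), then binned by max onto a G x G grid.
oracle_surface <- function(pairs, G) {
  n <- nrow(pairs)
  xs <- (pairs$x - mean(pairs$x)) / sd(pairs$x)
  ys <- (pairs$y - mean(pairs$y)) / sd(pairs$y)
  h <- xs + ys
  i <- rank(pairs$x, ties.method = "first")
  j <- rank(pairs$y, ties.method = "first")
  gmin <- min(h)
  zfull <- matrix(NA_real_, n, n)      # rows = y rank, cols = x rank
  occ <- matrix(FALSE, n, n)
  for (k in seq_len(n)) {
    zfull[j[k], i[k]] <- h[k]
    occ[j[k], i[k]] <- TRUE
  }
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (!occ[b, a]) {
        sub <- zfull[1:b, 1:a, drop = FALSE][occ[1:b, 1:a, drop = FALSE]]
        zfull[b, a] <- if (length(sub) > 0) max(sub) else gmin
      }
    }
  }
  z <- matrix(gmin, G, G)
  bi <- ceiling(seq_len(n) * G / n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      z[bi[b], bi[a]] <- max(z[bi[b], bi[a]], zfull[b, a])
    }
  }
  z
}

# Enumerate every (tx, ty) candidate on a surface matrix by direct block
# subsetting; returns the full candidate table.
oracle_profile_2d <- function(z) {
  G <- nrow(z)
  mu <- mean(z)
  out <- expand.grid(tx = seq_len(G - 1), ty = seq_len(G - 1))
  out$signal <- NA_real_
  out$noise <- NA_real_
  out$snr <- NA_real_
  for (r in seq_len(nrow(out))) {
    tx <- out$tx[r]; ty <- out$ty[r]
    f <- z
    f[1:ty, 1:tx] <- mean(z[1:ty, 1:tx])
    f[1:ty, (tx + 1):G] <- mean(z[1:ty, (tx + 1):G])
    f[(ty + 1):G, 1:tx] <- mean(z[(ty + 1):G, 1:tx])
    f[(ty + 1):G, (tx + 1):G] <- mean(z[(ty + 1):G, (tx + 1):G])
    signal <- sum((f - mu)^2)
    noise <- sum((f - z)^2)
    out$signal[r] <- signal
    out$noise[r] <- noise
    # shared zero-noise convention: rounding-level residuals are a perfect fit
    out$snr[r] <- if (noise <= 1e-9 * sum((z - mu)^2)) Inf else signal / noise
  }
  out
}

oracle_top_splits_2d <- function(profile, tol = 1e-9) {
  top <- max(profile$snr)
  keep <- if (is.infinite(top)) {
    best_sig <- max(profile$signal[is.infinite(profile$snr)])
    is.infinite(profile$snr) &
      profile$signal >= best_sig - tol * max(1, abs(best_sig))
  } else {
    profile$snr >= top - tol * max(1, top)
  }
  profile[keep, c("tx", "ty")]
}

# Term-by-term hypergeometric tail from binomial coefficients.
oracle_hyper_pvalue <- function(N, R, U, K) {
  k <- 0:K
  sum(choose(U, k) * choose(N - U, R - k)) / choose(N, R)
}

# Convenience: quadrant_counts object from margins N, R, U and count K.
counts_from_margins <- function(N, R, U, K) {
  new_quadrant_counts(
    upper_left = U - K,
    upper_right = K,
    lower_left = (N - R) - (U - K),
    lower_right = R - K
  )
}
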