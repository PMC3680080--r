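test_that("rank transform handles concordance, anti-concordance and ties", {
  p <- paired_series(x = c(10, 20, 30, 40), y = c(4, 3, 2, 1))
  rt <- rank_transform(p)
  expect_equal(rt$x_rank, 1:4)
  expect_equal(rt$y_rank, 4:1)

  p <- paired_series(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  rt <- rank_transform(p)
  expect_equal(rt$x_rank, rt$y_rank)

  # stable tie rule: earlier sample gets the smaller rank
  p <- paired_series(x = c(5, 5, 7, 6), y = c(1, 2, 3, 4),
                     ids = c("a", "b", "c", "d"))
  rt <- rank_transform(p)
  expect_equal(rt$x_rank, c(1L, 2L, 4L, 3L))
  # each axis is a permutation of 1..n
  expect_setequal(rt$x_rank, 1:4)
  expect_setequal(rt$y_rank, 1:4)
})

test_that("tiny surfaces match the hand-computed fill", {
  # diagonal pair: lower-left point floods its row and column
  p <- paired_series(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  s <- build_surface(p, grid_size = 2)
  h <- (p$x - mean(p$x)) / sd(p$x) + (p$y - mean(p$y)) / sd(p$y)
  expect_equal(s$z, matrix(c(h[2], h[2], h[2], h[4]), 2, 2))

  # anti-diagonal: empty lower-left cell takes the global minimum
  p <- paired_series(x = c(1, 2, 3, 4), y = c(4, 3, 2, 1))
  s <- build_surface(p, grid_size = 2)
  expect_equal(s$z[1, 1], s$global_min)
  expect_equal(s$global_min, min(h_of <- (p$x - mean(p$x)) / sd(p$x) +
                                   (p$y - mean(p$y)) / sd(p$y)))
})

test_that("binned surface equals the full-rank-resolution oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    G <- sample(2:6, 1)
    p <- paired_series(x = runif(n), y = runif(n))
    s <- build_surface(p, grid_size = G)
    expect_equal(s$z, oracle_surface(p, G), tolerance = 1e-12)
  }
})

test_that("every constructed surface is non-decreasing in both axes", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    G <- sample(c(2:10, 50), 1)
    p <- paired_series(x = rnorm(n), y = runif(n))
    z <- suppressWarnings(build_surface(p, grid_size = G))$z
    expect_true(all(diff(z) >= 0))        # down rows (y direction)
    expect_true(all(t(diff(t(z))) >= 0))  # across columns (x direction)
    expect_true(all(z >= min(z)))
  }
})

test_that("2D fit agrees with exhaustive enumeration on small grids", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    G <- sample(3:6, 1)
    p <- paired_series(x = runif(n), y = runif(n))
    s <- build_surface(p, grid_size = G)
    fit <- fit_step_2d(s)
    prof <- oracle_profile_2d(s$z)
    top <- oracle_top_splits_2d(prof)
    expect_true(any(top$tx == fit$tx & top$ty == fit$ty))
    ref <- prof[prof$tx == fit$tx & prof$ty == fit$ty, ]
    expect_equal(fit$snr, ref$snr, tolerance = 1e-9)
    expect_equal(fit$signal, ref$signal, tolerance = 1e-9)
  }
})

test_that("constant and zero-variance inputs are degenerate", {
  p <- tibble::tibble(x = c(1, 1, 1, 1), y = c(1, 2, 3, 4))
  expect_error(build_surface(p, 2), class = "stepminer2d_degenerate_input")
  s <- build_surface(paired_series(1:4, c(2, 1, 4, 3)), 2)
  s$z[] <- 1
  expect_error(fit_step_2d(s), class = "stepminer2d_degenerate_input")
})

test_that("monotone transforms preserve rank pairs; affine maps the full fit", {
  set.seed(51)
  p <- paired_series(x = rnorm(100), y = runif(100))
  fit <- stepminer2d(p, grid_size = 8)
  # any strictly increasing transform leaves the rank lattice unchanged
  p2 <- dplyr::mutate(p, x = exp(x))
  rt <- rank_transform(p); rt2 <- rank_transform(p2)
  expect_identical(rt$x_rank, rt2$x_rank)
  expect_identical(rt$y_rank, rt2$y_rank)
  # affine maps additionally leave the standardized heights -- and with them
  # the surface, the grid splits and the SNR -- unchanged
  p3 <- dplyr::mutate(p, x = 2.5 * x + 7)
  fit3 <- stepminer2d(p3, grid_size = 8)
  expect_identical(c(fit$tx, fit$ty), c(fit3$tx, fit3$ty))
  expect_equal(fit3$snr, fit$snr, tolerance = 1e-9)
  expect_equal(fit3$threshold_x, 2.5 * fit$threshold_x + 7, tolerance = 1e-9)
  expect_equal(fit3$threshold_y, fit$threshold_y)
})

test_that("swapping the two variables transposes the fit", {
  set.seed(61)
  p <- paired_series(x = rnorm(80), y = runif(80))
  swapped <- tibble::tibble(sample_id = p$sample_id, x = p$y, y = p$x)
  s <- build_surface(p, grid_size = 6)
  s_sw <- build_surface(swapped, grid_size = 6)
  expect_equal(s_sw$z, t(s$z))
  fit <- stepminer2d(p, grid_size = 6)
  fit_sw <- stepminer2d(swapped, grid_size = 6)
  expect_identical(c(fit_sw$tx, fit_sw$ty), c(fit$ty, fit$tx))
  expect_equal(c(fit_sw$threshold_x, fit_sw$threshold_y),
               c(fit$threshold_y, fit$threshold_x))
  expect_equal(fit_sw$snr, fit$snr, tolerance = 1e-9)
})

test_that("data-scale thresholds reproduce rank-space quadrant counts", {
  set.seed(71)
  p <- paired_series(x = rnorm(200), y = runif(200))
  G <- 10
  fit <- stepminer2d(p, grid_size = G)
  s <- build_surface(p, grid_size = G)
  rt <- rank_transform(p)
  rx <- s$x_bin_edges[fit$tx + 1]
  ry <- s$y_bin_edges[fit$ty + 1]
  # thresholds sit strictly between consecutive order statistics
  xs <- sort(p$x); ys <- sort(p$y)
  expect_true(xs[rx] <= fit$threshold_x && fit$threshold_x <= xs[rx + 1])
  expect_true(ys[ry] <= fit$threshold_y && fit$threshold_y <= ys[ry + 1])
  # counting on data scale == counting on rank space at the cut ranks
  data_counts <- tidy(quadrant_counts(p$y, p$x, fit$threshold_y,
                                      fit$threshold_x))
  rank_counts <- tidy(quadrant_counts(as.numeric(rt$y_rank),
                                      as.numeric(rt$x_rank),
                                      ry + 0.5, rx + 0.5))
  expect_equal(data_counts, rank_counts)
})

test_that("silencing-structured pairs recover a threshold between the modes", {
  gp <- gen_pair(400, seed = 81, type = "silencing",
                 beta_meth_shape = c(40, 10), beta_unmeth_shape = c(5, 95))
  fit <- stepminer2d(gp$pairs)
  expect_gt(fit$threshold_y, 0.05)   # unmethylated mode centre
  expect_lt(fit$threshold_y, 0.80)   # methylated mode centre
  expect_gt(fit$snr, 3)              # strongly multi-modal joint distribution
})

test_that("few samples relative to the grid warns and clamps thresholds", {
  p <- paired_series(x = c(1, 3, 2, 4, 6), y = c(2, 1, 4, 3, 5))
  expect_warning(build_surface(p, grid_size = 8), "Fewer samples")
  fit <- suppressWarnings(stepminer2d(p, grid_size = 8))
  expect_true(is.finite(fit$threshold_x) && is.finite(fit$threshold_y))
})
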