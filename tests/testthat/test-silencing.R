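test_that("quadrant counting follows the <=-is-low/unmethylated convention", {
  cts <- quadrant_counts(meth = c(0, 0, 1, 1), expr = c(0, 1, 0, 1),
                         meth_threshold = 0.5, expr_threshold = 0.5)
  expect_equal(tidy(cts)[, c("upper_left", "upper_right", "lower_left",
                             "lower_right")],
               tibble::tibble(upper_left = 1L, upper_right = 1L,
                              lower_left = 1L, lower_right = 1L))
  expect_equal(cts$n_total, 4L)
  expect_equal(cts$r_methylated, 2L)
  expect_equal(cts$u_high, 2L)

  all_low <- quadrant_counts(c(0.1, 0.2), c(0.1, 0.2), 0.5, 0.5)
  expect_equal(all_low$lower_left, 2L)

  # values tied with a threshold fall low/unmethylated
  tied <- quadrant_counts(c(0.5, 0.6), c(0.5, 0.6), 0.5, 0.5)
  expect_equal(tied$lower_left, 1L)
  expect_equal(tied$upper_right, 1L)

  expect_error(quadrant_counts(numeric(0), numeric(0), 0.5, 0.5),
               class = "stepminer2d_invalid_input")
})

test_that("quadrant counts are invariant to joint monotone transforms", {
  set.seed(5)
  meth <- runif(100); expr <- rnorm(100)
  a <- tidy(quadrant_counts(meth, expr, 0.4, 0.3))
  b <- tidy(quadrant_counts(meth^3, exp(expr), 0.4^3, exp(0.3)))
  expect_equal(a, b)
})

test_that("counts computed from generator truth match its labels", {
  gp <- gen_pair(1000, seed = 9, type = "silencing",
                 beta_meth_shape = c(80, 20), beta_unmeth_shape = c(5, 95),
                 expr_high_mean = 6, expr_low_mean = 0, expr_sd = 0.3)
  # thresholds placed between the well-separated modes
  cts <- quadrant_counts(gp$pairs$y, gp$pairs$x, 0.45, 3)
  expect_equal(cts$upper_right, sum(gp$truth$quadrant == "upper_right"))
  expect_equal(cts$lower_right, sum(gp$truth$quadrant == "lower_right"))
  expect_equal(cts$upper_left, sum(gp$truth$quadrant == "upper_left"))
  expect_equal(cts$lower_left, sum(gp$truth$quadrant == "lower_left"))
})

test_that("hypergeometric p-value matches term-by-term enumeration", {
  # the worked example N=10, R=4, U=5, K=1
  cts <- counts_from_margins(10, 4, 5, 1)
  expect_equal(hypergeom_pvalue(cts),
               (choose(5, 0) * choose(5, 4) + choose(5, 1) * choose(5, 3)) /
                 choose(10, 4))

  set.seed(13)
  for (rep in 1:200) {
    N <- sample(1:60, 1)
    R <- sample(0:N, 1)
    U <- sample(0:N, 1)
    ks <- max(0, R + U - N):min(R, U)
    K <- ks[sample.int(length(ks), 1)]
    expect_equal(hypergeom_pvalue(counts_from_margins(N, R, U, K)),
                 oracle_hyper_pvalue(N, R, U, K), tolerance = 1e-12)
  }
})

test_that("full-support and empty-margin tables give p = 1 exactly", {
  expect_identical(hypergeom_pvalue(counts_from_margins(20, 8, 5, 5)), 1)
  expect_identical(hypergeom_pvalue(counts_from_margins(20, 5, 8, 5)), 1)
  # no methylated samples: the only possible table
  expect_identical(hypergeom_pvalue(counts_from_margins(50, 0, 20, 0)), 1)
  # no high-expression samples
  expect_identical(hypergeom_pvalue(counts_from_margins(50, 20, 0, 0)), 1)
})

test_that("p-value is monotone non-decreasing in the upper-right count", {
  for (margins in list(c(30, 12, 9), c(60, 40, 35), c(25, 25, 25))) {
    N <- margins[1]; R <- margins[2]; U <- margins[3]
    ks <- max(0, R + U - N):min(R, U)
    ps <- vapply(ks, function(K) {
      hypergeom_pvalue(counts_from_margins(N, R, U, K))
    }, numeric(1))
    expect_true(all(diff(ps) >= 0))
    expect_equal(ps[length(ps)], 1)
  }
})

test_that("inconsistent margins are rejected", {
  bad <- counts_from_margins(20, 5, 8, 5)
  bad$k_upper_right <- 7   # exceeds min(R, U)
  expect_error(hypergeom_pvalue(bad), class = "stepminer2d_invalid_input")
  expect_error(new_quadrant_counts(-1, 2, 3, 4),
               class = "stepminer2d_invalid_input")
})

test_that("permutation null keeps the one-sided test calibrated", {
  set.seed(17)
  n <- 200
  meth_high <- c(rep(TRUE, 70), rep(FALSE, n - 70))
  expr_high <- c(rep(TRUE, 90), rep(FALSE, n - 90))
  ps <- replicate(2000, {
    perm <- sample(expr_high)
    cts <- new_quadrant_counts(
      upper_left = sum(perm & !meth_high),
      upper_right = sum(perm & meth_high),
      lower_left = sum(!perm & !meth_high),
      lower_right = sum(!perm & meth_high)
    )
    hypergeom_pvalue(cts)
  })
  rate <- mean(ps < 0.05)
  # conservative discrete test: at or below nominal within binomial error
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(rate, 0.005)
})

test_that("direction filter excludes only a strict >10% excess", {
  excl <- new_quadrant_counts(upper_left = 30, upper_right = 25,
                              lower_left = 10, lower_right = 35)
  expect_true(direction_filter(excl))            # 15 > 10
  eq <- new_quadrant_counts(upper_left = 40, upper_right = 20,
                            lower_left = 20, lower_right = 20)
  expect_false(direction_filter(eq))             # difference 0
  boundary <- new_quadrant_counts(upper_left = 35, upper_right = 20,
                                  lower_left = 10, lower_right = 35)
  expect_false(direction_filter(boundary))       # exactly 10, not more
  expect_error(direction_filter(eq, fraction = 1.5),
               class = "stepminer2d_invalid_input")
})

test_that("Bonferroni flags strictly below alpha/m", {
  expect_equal(bonferroni_significant(0.005, alpha = 0.01), TRUE)
  expect_equal(bonferroni_significant(c(0.006, 0.004), alpha = 0.01),
               c(FALSE, TRUE))
  # a family of 11,189 tests: cutoff is alpha/m, near 8.94e-7
  set.seed(23)
  p <- runif(11189, 0, 3e-6)
  expect_equal(bonferroni_significant(p, alpha = 0.01), p < 0.01 / 11189)
  p <- runif(500, 0, 1e-4)
  expect_equal(bonferroni_significant(p, alpha = 0.01), p < 0.01 / 500)
  expect_error(bonferroni_significant(numeric(0)),
               class = "stepminer2d_invalid_input")
})

test_that("pan and per-group testing finds group-confined associations", {
  # group A silencing, group B entirely unmethylated
  gA <- gen_pair(200, seed = 31, type = "silencing",
                 beta_meth_shape = c(40, 10), beta_unmeth_shape = c(5, 95))
  gB <- gen_pair(200, seed = 32, type = "silencing", frac_meth = 0,
                 beta_meth_shape = c(40, 10), beta_unmeth_shape = c(5, 95))
  pairs <- dplyr::bind_rows(
    dplyr::mutate(gA$pairs, sample_id = paste0("A", sample_id)),
    dplyr::mutate(gB$pairs, sample_id = paste0("B", sample_id))
  )
  groups <- rep(c("A", "B"), each = 200)
  fit <- stepminer2d(pairs)
  res <- test_pair(pairs, fit, groups = groups)
  expect_equal(res$group, c("pan", "A", "B"))
  pA <- res$p_value[res$group == "A"]
  pB <- res$p_value[res$group == "B"]
  expect_lt(pA, 0.01 / 200)
  # B has (almost) no methylated samples -- at most a few boundary calls
  # from the grid-quantized threshold -- hence essentially no evidence
  r_B <- res$upper_right[res$group == "B"] +
    res$lower_right[res$group == "B"]
  expect_lte(r_B, ceiling(0.03 * 200))
  expect_gt(pB, 0.1)
  # with a threshold clear of the unmethylated tail the margin is empty
  # and the p-value is exactly 1
  ctsB <- quadrant_counts(gB$pairs$y, gB$pairs$x, 0.5, fit$threshold_x)
  expect_equal(ctsB$r_methylated, 0L)
  expect_equal(hypergeom_pvalue(ctsB), 1)
})

test_that("groups default to a single pan row; tiny groups are untestable", {
  set.seed(37)
  p <- paired_series(x = rnorm(50), y = runif(50))
  fit <- suppressWarnings(stepminer2d(p, grid_size = 10))
  expect_identical(nrow(test_pair(p, fit)), 1L)
  groups <- c("solo", rep("rest", 49))
  res <- test_pair(p, fit, groups = groups)
  expect_true(res$untestable[res$group == "solo"])
  expect_false(res$untestable[res$group == "rest"])
})

test_that("per-group refit mode produces group-specific thresholds", {
  set.seed(41)
  g1 <- gen_pair(150, seed = 43, type = "silencing")
  g2 <- gen_pair(150, seed = 44, type = "silencing",
                 beta_meth_shape = c(20, 30),  # methylated mode near 0.4
                 beta_unmeth_shape = c(2, 60))
  pairs <- dplyr::bind_rows(
    dplyr::mutate(g1$pairs, sample_id = paste0("g1_", sample_id)),
    dplyr::mutate(g2$pairs, sample_id = paste0("g2_", sample_id))
  )
  groups <- rep(c("g1", "g2"), each = 150)
  fit <- stepminer2d(pairs)
  res_pan <- test_pair(pairs, fit, groups = groups)
  res_refit <- test_pair(pairs, fit, groups = groups,
                         per_group_thresholds = "refit")
  expect_equal(res_pan$threshold_y[res_pan$group != "pan"],
               rep(fit$threshold_y, 2))
  expect_false(isTRUE(all.equal(
    res_refit$threshold_y[res_refit$group == "g1"],
    res_refit$threshold_y[res_refit$group == "g2"]
  )))
})
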