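test_that("min-max scaling maps extremes to 0 and 1 and preserves order", {
  expect_equal(minmax_scale(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(3, 1, 2)), c(1, 0, 0.5))
  expect_error(minmax_scale(c(7, 7, 7)), "degenerate range")
  expect_error(minmax_scale(c(1, NA, 3)), "non-finite")
})

test_that("incremental rates follow the five-step pipeline by hand", {
  # identity relation: shared scaling makes every rate 1 (gaps kept
  # above the dx threshold so no NaN enters)
  set.seed(1)
  x <- cumsum(runif(20, 0.05, 0.8)) - 3
  tr <- incremental_rates(x, x)
  expect_equal(tr$rate_scaled, rep(1, 19))
  # worked example through all steps
  tr2 <- incremental_rates(c(0, 1, 2), c(0, 1, 4))
  expect_equal(tr2$rate_scaled, c(1 / 3, 1))
  # duplicated x values yield NaN rates via the threshold rule
  tr3 <- incremental_rates(c(0, 1, 1, 2), c(0, 1, 2, 3))
  expect_true(is.nan(tr3$rate[2]))
  expect_false(any(is.nan(tr3$rate[c(1, 3)])))
  # degenerate: on a dense uniform grid every scaled increment is below
  # the 1e-3 threshold
  g <- seq_len(1500) / 1500
  expect_error(incremental_rates(g, g), "no valid increments")
})

test_that("moving average shrinks at edges and skips NaN", {
  expect_equal(moving_average(rep(4.2, 10), 5), rep(4.2, 10))
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 5)[3], 3)
  expect_equal(moving_average(c(1, NaN, 3), 3)[2], 2)
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 5)[1], mean(1:3))
  expect_true(is.nan(moving_average(c(NaN, NaN, NaN), 3)[2]))
  expect_error(moving_average(1:5, 4), "parameter error")
})

test_that("pipeline matches the naive loop reference bit-for-bit", {
  set.seed(7)
  for (case in 1:12) {
    n <- sample(5:50, 1)
    x <- runif(n)
    y <- switch(case %% 3 + 1,
                2 * x + rnorm(n, 0, 0.2),
                1 - exp(-4 * x) + rnorm(n, 0, 0.05),
                rnorm(n))
    if (case %% 4 == 0) x[2] <- x[1]       # force a tie
    got <- incremental_rates(x, y)$rate_scaled
    ref <- naive_rate_pipeline(x, y)
    expect_identical(got, ref)
  }
})

test_that("outputs are invariant to affine input maps and row order", {
  set.seed(8)
  x <- runif(200); y <- 1 - exp(-3 * x) + rnorm(200, 0, 0.05)
  base <- run_saturation_analysis(x, y)
  aff <- run_saturation_analysis(5 * x - 2, 0.1 * y + 7)
  expect_equal(aff$rate_scaled, base$rate_scaled, tolerance = 1e-12)
  expect_equal(aff$rate_smoothed, base$rate_smoothed, tolerance = 1e-12)
  expect_identical(aff$peak_x, base$peak_x)
  perm <- sample(200)
  per <- run_saturation_analysis(x[perm], y[perm])
  expect_equal(per$rate_scaled, base$rate_scaled, tolerance = 1e-12)
  expect_identical(per$peak_x, base$peak_x)
})

test_that("top-fraction density localises the high-nitrogen samples", {
  # point mass: degenerate flag, the single x returned
  d <- top_fraction_density(rep(0.7, 40), c(rep(0.1, 20), rep(0.95, 20)))
  expect_true(d$degenerate)
  expect_equal(d$peak_x, 0.7)
  # narrow Gaussian: peak within 0.02 of the centre
  set.seed(9)
  xt <- pmin(pmax(rnorm(500, 0.68, 0.05), 0), 1)
  xlow <- runif(1500)
  d2 <- top_fraction_density(c(xt, xlow),
                             c(rep(0.95, 500), rep(0.3, 1500)))
  expect_false(d2$degenerate)
  expect_equal(d2$peak_x, 0.68, tolerance = 0.02)
  # independent oracle: argmax of the analytic Gaussian KDE on its grid
  h <- sd(xt) * length(xt)^(-1 / 5)
  grid <- seq(0, 1, length.out = 512)
  dens <- sapply(grid, function(g) mean(dnorm((g - xt) / h)) / h)
  expect_identical(d2$peak_x, grid[which.max(dens)])
  # linear data: the top of Y occupies the top of X
  set.seed(10)
  x <- runif(3000)
  d3 <- top_fraction_density(x, x)
  expect_gte(d3$peak_x, 0.8)
})

test_that("full analysis separates linear, saturating and inverted inputs", {
  set.seed(11)
  # spacing kept above the scaled dx threshold (no NaN rates)
  x <- cumsum(runif(400, 0.8, 1.2))
  x <- (x - min(x)) / diff(range(x))
  lin <- run_saturation_analysis(x, x)
  expect_equal(lin$summary_ratio, 1, tolerance = 1e-9)
  expect_gte(lin$peak_x, 0.8)
  sat <- run_saturation_analysis(x, 1 - exp(-5 * x))
  expect_lt(sat$summary_ratio, 0.5)
  expect_lt(sat$peak_x, lin$peak_x)
  dec <- run_saturation_analysis(x, 1 - x)
  expect_equal(dec$rate_scaled, rep(-1, 399))
  expect_false(is.nan(dec$summary_ratio))
  expect_equal(dec$summary_ratio, 1, tolerance = 1e-9)
})

test_that("parameter object validates its domain", {
  expect_error(saturation_params(smooth_window = 4), "parameter error")
  expect_error(saturation_params(top_fraction = 1.2), "top_fraction")
  expect_error(saturation_params(dx_threshold = 0), "dx_threshold")
  expect_error(saturation_params(kde_bandwidth = -1), "bandwidth")
})
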