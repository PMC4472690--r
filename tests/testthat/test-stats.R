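test_that("pearson matches the product-moment formula and its contract", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)

  xs <- c(1, 2, 3, 4, 5)
  ys <- c(2, 1, 4, 3, 6)
  # direct evaluation of the product-moment formula, no cor()
  num <- sum((xs - mean(xs)) * (ys - mean(ys)))
  den <- sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(pearson(xs, ys), num / den)

  # missing pairs dropped before anything else
  expect_equal(pearson(c(xs, NA), c(ys, 5)), num / den)
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("cross-correlation is normalized, antisymmetric, and unit at lag 0", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(10)
    y <- rnorm(10)
    cc <- cross_correlation(x, y, lags = -3:3)
    expect_true(all(abs(cc$values) <= 1 + 1e-9))
    # antisymmetry C_xy(-k) = C_yx(k), exactly
    rev_cc <- cross_correlation(y, x, lags = -3:3)
    expect_identical(cc$values, rev(rev_cc$values))
    expect_equal(cross_correlation(x, x)$values[2], 1)
  }

  expect_equal(cross_correlation(1:4, 4:1)$values[2], -1)

  # a pulse shifted by one step peaks at lag +1
  cc <- cross_correlation(c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(cc$best_lag, 1L)

  # brute-force check of the printed-formula evaluation at each lag
  x <- c(2, 4, 1, 7, 3, 5)
  y <- c(1, 3, 6, 2, 8, 4)
  n <- length(x)
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  for (k in 0:2) {
    manual <- sum((x[1:(n - k)] - mean(x)) * (y[(1 + k):n] - mean(y))) / n / (sx * sy)
    expect_equal(cross_correlation(x, y, lags = k:k)$values, manual)
  }

  expect_error(cross_correlation(rep(1, 5), 1:5), "constant")
  expect_error(cross_correlation(1:5, 1:5, lags = 5), "smaller than")
  expect_error(cross_correlation(1:4, 1:5), "equal length")
})

test_that("windowing shift moves the arg-max lag accordingly", {
  pulse <- c(0, 0, 0, 4, 5, 4, 0, 0, 0, 0)
  shifted <- c(0, 0, 0, 0, 4, 5, 4, 0, 0, 0) # pulse one window later
  expect_equal(cross_correlation(pulse, pulse)$best_lag, 0L)
  expect_equal(cross_correlation(pulse, shifted)$best_lag, 1L)
  expect_equal(cross_correlation(shifted, pulse)$best_lag, -1L)
})

test_that("best lag picks the strongest positive value with lag-0 fallback", {
  b <- best_lag(c(-.135, .855, .104))
  expect_equal(b$lag, 0L)
  expect_equal(b$value, .855)

  b <- best_lag(c(.104, -.135, .855)) # strongest positive at +1
  expect_equal(b$lag, 1L)

  b <- best_lag(c(-.5, -.2, -.1)) # none positive: lag 0 with its value
  expect_equal(b$lag, 0L)
  expect_equal(b$value, -.2)

  b <- best_lag(c(.3, .3, .1)) # exact tie prefers lag 0
  expect_equal(b$lag, 0L)
  expect_equal(b$value, .3)
})

test_that("one-sample summary computes t, df and d, and round-trips", {
  s <- one_sample_summary(mean = .562, sd = .213, n = 27)
  expect_equal(s$t, .562 / (.213 / sqrt(27)))
  expect_equal(s$df, 26L)
  expect_equal(s$d, .562 / .213)

  z <- one_sample_summary(mean = 0, sd = 1, n = 10)
  expect_equal(z$t, 0)
  expect_equal(z$d, 0)

  set.seed(8)
  x <- rnorm(27, 0.5, 0.2)
  from_raw <- one_sample_summary(x)
  from_triple <- one_sample_summary(mean = mean(x), sd = sd(x), n = length(x))
  expect_equal(from_raw, from_triple)

  expect_error(one_sample_summary(mean = 1, sd = 0, n = 5), "SD")
  expect_error(one_sample_summary(mean = 1, sd = 1, n = 1), "n >= 2")
})

test_that("outlying series are flagged at the group level", {
  expect_false(any(flag_outlying_series(rep(3, 5))))
  v <- c(rep(0, 9), 5) # z = 3 > 2
  expect_equal(which(flag_outlying_series(v)), 10L)
  expect_false(any(flag_outlying_series(c(1, 1.2, 0.9, 1.1))))
  expect_error(flag_outlying_series(c(1, 2)), "at least 3")
})

test_that("percentile subsetting excludes ceiling(n*p/100) smallest by rank", {
  set.seed(4)
  v <- rnorm(27)
  ps <- percentile_subset(v, 25)
  expect_length(ps$excluded, 7L)
  expect_length(ps$kept, 20L)
  expect_true(max(v[ps$excluded]) <= min(v[ps$kept]))

  expect_length(percentile_subset(rnorm(4), 25)$excluded, 1L)

  ties <- rep(1, 8) # all equal: rank rule still excludes exactly 2
  ps2 <- percentile_subset(ties, 25)
  expect_equal(ps2$excluded, c(1L, 2L)) # ties broken by original order
})

test_that("tidy and glance views expose the correlation profile", {
  cc <- cross_correlation(c(0, 1, 0, 2), c(0, 1, 0, 2))
  td <- tidy(cc)
  expect_equal(td$lag, -1:1)
  expect_equal(td$correlation[td$lag == 0], 1)
  expect_true(td$is_best[td$lag == 0])
  gl <- glance(cc)
  expect_equal(gl$best_lag, 0L)
  expect_equal(gl$lag0, 1)
  expect_equal(gl$n_windows, 4L)
})
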