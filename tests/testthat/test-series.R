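test_that("fixed burn-in removes round(seconds * rate) samples", {
  s <- tibble::tibble(value = rnorm(100))
  out <- discard_burn_in(s, rate_hz = 30, burn_in_seconds = 1)
  expect_equal(nrow(out), 70L)
  expect_equal(out$value, s$value[31:100])

  expect_equal(discard_burn_in(s, rate_hz = 30, burn_in_seconds = 0), s)
  expect_equal(nrow(discard_burn_in(s, burn_in_samples = 5)), 95L)
  expect_error(discard_burn_in(s, burn_in_samples = 100), "whole series")
  expect_error(discard_burn_in(s, burn_in_seconds = 1), "rate_hz")
})

test_that("auto burn-in strips the leading run of high z-scores", {
  v <- c(9, 9, rep(0, 48))
  out <- discard_burn_in(v, auto = TRUE, z_threshold = 2.5)
  expect_equal(nrow(out), 48L) # hand check: z of 9 vs full-series mean/SD > 2.5
  expect_true(all(out$value == 0))

  # nothing leading-high: unchanged
  flat <- c(0, 0, 9, rep(0, 47))
  expect_equal(nrow(discard_burn_in(flat, auto = TRUE)), 50L)
})

test_that("outlier removal is one two-sided pass with sample SD", {
  const <- rep(5, 10)
  out <- remove_outliers(const)
  expect_false(any(out$outlier)) # SD = 0 flags nothing
  expect_equal(outlier_fraction(out), 0)

  v <- c(rep(0, 9), 10) # z of the 10 is about 2.85
  out <- remove_outliers(v, z_threshold = 2.5)
  expect_equal(which(out$outlier), 10L)
  expect_true(is.na(out$value[10]))
  expect_equal(outlier_fraction(out), 0.1)

  tame <- sin(1:50) # everything well within 2.5 SD
  expect_false(any(remove_outliers(tame)$outlier))

  # the rule is a single pass by contract: re-applying it with the
  # post-blanking mean/SD can flag values the first pass kept
  v2 <- c(rep(0, 20), 5, 100)
  p1 <- remove_outliers(v2)
  expect_equal(which(p1$outlier), 22L)
  p2 <- remove_outliers(p1)
  expect_true(p2$outlier[21])

  expect_error(remove_outliers(c(1, NA)), "non-missing")
})

test_that("absolute difference shrinks length by one and propagates NA", {
  expect_equal(absolute_difference(c(0.1, 0.3))$value, 0.2)
  expect_equal(nrow(absolute_difference(5)), 0L)
  expect_equal(
    absolute_difference(c(0.1, NA, 0.4))$value,
    c(NA_real_, NA_real_)
  )
  set.seed(2)
  v <- rnorm(40)
  d <- absolute_difference(v)$value
  expect_length(d, 39L)
  expect_true(all(d >= 0))
})

test_that("euclidean norm collapses three axes to a magnitude", {
  d <- tibble::tibble(x = c(0, 3), y = c(0, 4), z = c(0, 12))
  expect_equal(euclidean_norm(d)$value, c(0, 13))
  # invariant to axis permutation
  perm <- tibble::tibble(x = d$z, y = d$x, z = d$y)
  expect_equal(euclidean_norm(perm)$value, euclidean_norm(d)$value)
  expect_error(euclidean_norm(tibble::tibble(x = 1, y = 2)), "x, y and z")
})

test_that("mean_grid averages all sensing elements per frame", {
  g <- matrix(c(1, 2, 3, 6), 2, 2)
  expect_equal(mean_grid(list(g))$value, 3)
  expect_equal(mean_grid(array(0, dim = c(3, 3, 2)))$value, c(0, 0))
  expect_equal(mean_grid(array(7, dim = c(38, 41, 3)))$value, rep(7, 3))
})

test_that("window means use floor width, drop the tail, ignore NA", {
  w <- window_means(1:20, k = 10)
  expect_equal(w$mean, seq(1.5, 19.5, by = 2))
  expect_equal(attr(w, "window_width"), 2L)

  expect_equal(window_means(1:10, k = 10)$mean, as.numeric(1:10))

  w23 <- window_means(1:23, k = 10)
  expect_equal(attr(w23, "window_width"), 2L) # last 3 samples dropped
  expect_equal(w23$mean[10], mean(19:20))

  v <- c(1, NA, 3, NA, NA, NA) # second window all-missing
  w2 <- window_means(v, k = 2)
  expect_equal(w2$mean, c(2, NA))

  expect_equal(window_means(rep(4, 30), k = 10)$mean, rep(4, 10))
  expect_error(window_means(1:5, k = 10), "too short")
  expect_error(window_means(1:5, k = 1), "k must be >= 2")
})

test_that("series_mean ignores missing and rejects all-missing", {
  expect_equal(series_mean(c(1, 2, 3)), 2)
  expect_equal(series_mean(c(1, NA, 3)), 2)
  expect_error(series_mean(c(NA_real_, NA_real_)), "all values are missing")
})

test_that("prepare_series applies burn-in, outliers, then differencing", {
  set.seed(9)
  v <- c(50, 50, rnorm(118)) # hot burn-in start
  out <- prepare_series(v, rate_hz = 2, burn_in_seconds = 1, diff = TRUE)
  expect_equal(nrow(out), 117L) # 120 - 2 burn-in - 1 differencing
  expect_true(all(out$value >= 0 | is.na(out$value)))
  # burn-in discard never changes later values
  out2 <- prepare_series(c(99, v), rate_hz = 2, burn_in_samples = 3, diff = TRUE)
  expect_equal(out2$value, out$value)

  nd <- prepare_series(v, rate_hz = 2, burn_in_seconds = 1, diff = FALSE)
  expect_equal(nrow(nd), 118L)
})

test_that("series and pressure-grid text formats round-trip", {
  d <- tibble::tibble(timestamp_ms = c(0, 250, 500), value = c(1, NA, 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(d, p)
  expect_equal(as.data.frame(read_series_csv(p)), as.data.frame(d))

  set.seed(3)
  g <- array(round(runif(38 * 41 * 4, 0, 255)), dim = c(38, 41, 4))
  gp <- withr::local_tempfile(fileext = ".grid")
  write_pressure_grid(g, gp, rate_hz = 4)
  back <- read_pressure_grid(gp)
  expect_equal(back$frames, g)
  expect_equal(back$rate_hz, 4)
})
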