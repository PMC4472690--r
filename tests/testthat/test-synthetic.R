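test_that("movement profiles are seeded, nonnegative and bounded", {
  p1 <- movement_profile(300, "bursts", seed = 42)
  p2 <- movement_profile(300, "bursts", seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1$displacement >= 0))
  expect_true(all(p1$displacement <= 4))

  pc <- movement_profile(50, "constant", displacement = 3)
  expect_equal(pc$displacement, rep(3, 50))

  pw <- movement_profile(200, "random_walk", max_displacement = 2, seed = 1)
  expect_true(all(pw$displacement %in% 0:2))
  expect_true(all(abs(diff(pw$displacement)) <= 1))
})

test_that("a static, low-noise scene yields zero motion index throughout", {
  prof <- movement_profile(300, "constant", displacement = 0)
  vid <- generate_motion_video(prof, scene_config(noise_sd = 3), seed = 5)
  expect_equal(vid$truth$changed_pixels, rep(0L, 299))
  s <- process_video(vid, tracker_config())
  expect_equal(s$motion_index, rep(0, 299))
})

test_that("an object jumping its own width changes exactly 2k pixels", {
  # width chosen so the bouncing grid tiles the frame with no partial overlap
  sc <- scene_config(
    width = 64, height = 16, object_width = 8, object_height = 8,
    noise_sd = 0
  )
  prof <- movement_profile(20, "constant", displacement = 8)
  vid <- generate_motion_video(prof, sc)
  k <- 8 * 8
  expect_equal(vid$truth$changed_pixels, rep(2L * k, 19))
  # with N of one frame interval the engine sees the same 2k
  s <- process_video(vid, tracker_config(mhi_duration_ms = 1))
  expect_equal(s$motion_index, rep(2 * k / (64 * 16), 19))
})

test_that("video generation is bit-identical under a fixed seed", {
  prof <- movement_profile(60, "bursts", seed = 3)
  v1 <- generate_motion_video(prof, scene_config(), seed = 10)
  v2 <- generate_motion_video(prof, scene_config(), seed = 10)
  expect_identical(v1$frames, v2$frames)
  expect_true(all(v1$frames >= 0 & v1$frames <= 255))

  expect_error(
    scene_config(width = 10, object_width = 12),
    "does not fit"
  )
  sc_full <- scene_config(width = 12, object_width = 12)
  expect_error(
    generate_motion_video(movement_profile(10, "constant", displacement = 1), sc_full),
    "cannot move"
  )
})

test_that("noise-free sensors recover the profile exactly", {
  prof <- movement_profile(90, "bursts", fps = 30, seed = 7)

  # scalar at the frame rate: windowed cross-correlation with the profile is 1
  s0 <- generate_sensor_series(prof, sensor_config(rate_hz = 30, noise_sd = 0))
  cc <- cross_correlation(window_means(s0, k = 10), window_means(prof$displacement, k = 10))
  expect_equal(cc$values[cc$lags == 0], 1)

  # tri-axis: Euclidean norm equals gain * profile samplewise
  tri <- generate_sensor_series(
    prof,
    sensor_config(rate_hz = 30, noise_sd = 0, channels = "tri_axis", gain = 2)
  )
  expect_equal(euclidean_norm(tri)$value, 2 * prof$displacement)

  # grid: mean pressure equals gain * profile, pressures nonnegative
  g <- generate_sensor_series(
    prof,
    sensor_config(rate_hz = 30, noise_sd = 0, channels = "grid", gain = 1.5)
  )
  expect_equal(dim(g$frames)[1:2], c(38L, 41L))
  expect_true(all(g$frames >= 0))
  expect_equal(mean_grid(g$frames)$value, 1.5 * prof$displacement)
})

test_that("sensor length matches duration times rate to within one sample", {
  prof <- movement_profile(1800, "constant", displacement = 1, fps = 30)
  for (rate in c(4, 30, 50)) {
    s <- generate_sensor_series(prof, sensor_config(rate_hz = rate, noise_sd = 0))
    expect_lte(abs(nrow(s) - 60 * rate), 1)
  }
})

test_that("a sensor lag of one window width moves the best lag off zero", {
  prof <- movement_profile(1800, "bursts", fps = 30, seed = 21)
  lagged <- generate_sensor_series(
    prof,
    sensor_config(rate_hz = 4, noise_sd = 0, lag_s = 6), # one of 10 windows of 60 s
    seed = 22
  )
  aligned <- generate_sensor_series(
    prof,
    sensor_config(rate_hz = 4, noise_sd = 0),
    seed = 22
  )
  wp <- window_means(prof$displacement, k = 10)
  expect_equal(cross_correlation(wp, window_means(aligned, k = 10))$best_lag, 0L)
  expect_equal(cross_correlation(wp, window_means(lagged, k = 10))$best_lag, 1L)
})

test_that("increasing sensor noise degrades the recovered correlation", {
  prof_for <- function(seed) movement_profile(600, "bursts", fps = 30, seed = seed)
  med <- sapply(c(0, 2, 10), function(ns) {
    stats::median(sapply(1:8, function(seed) {
      prof <- prof_for(seed)
      s <- generate_sensor_series(
        prof, sensor_config(rate_hz = 4, noise_sd = ns),
        seed = 100 + seed
      )
      cc <- cross_correlation(
        window_means(prof$displacement, k = 10),
        window_means(s, k = 10)
      )
      cc$values[cc$lags == 0]
    }))
  })
  expect_true(all(diff(med) < 0))
})

test_that("simulate_fixture writes video, sensor, truth and manifest", {
  dir <- withr::local_tempdir()
  res <- simulate_fixture(dir, duration_s = 2, seed = 9)
  expect_true(all(file.exists(
    c(res$video, res$sensor, res$truth, res$manifest)
  )))
  manifest <- read_run_config(res$manifest)
  expect_equal(manifest$seed, 9)
  expect_equal(manifest$duration_s, 2)
  expect_equal(manifest$sensor_channels, "scalar")

  back <- read_avi(res$video)
  expect_equal(dim(back$frames), c(64L, 64L, 60L))
  expect_identical(back$frames, res$objects$video$frames)

  expect_error(simulate_fixture(dir, duration_s = 0), "duration_s")
})
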