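# Seeded generators of synthetic videos and co-registered sensor streams
# sharing a latent movement profile. These emulate the structure of the
# validation recordings — 30 fps video of a subject moving against a
# quasi-static background, paired with a contact-sensor stream at 4-50 Hz
# carrying the same latent movement plus noise — so the whole pipeline is
# testable without any real recordings.

#' Latent movement profile
#'
#' The ground-truth "how much the subject moves" signal, expressed as a
#' nonnegative per-frame displacement in pixels. Three kinds:
#'
#' * `"bursts"` — alternating active / quiet segments of random length
#'   (uniform in `segment_seconds`), each active with probability
#'   `p_active`; within an active segment the per-frame displacement is
#'   drawn uniformly from `0:A` with a per-segment amplitude `A` drawn from
#'   `1:max_displacement`. This mimics a person alternating between stillness
#'   and fidgeting/shifting of varying vigour.
#' * `"constant"` — fixed displacement every frame.
#' * `"random_walk"` — displacement follows a reflected random walk on
#'   `0:max_displacement`.
#'
#' @param n_frames Number of video frames the profile spans.
#' @param kind Profile kind (see above).
#' @param displacement Displacement for `kind = "constant"` (pixels/frame).
#' @param max_displacement Maximum displacement for the stochastic kinds.
#' @param fps Frame rate the profile is defined against (default 30).
#' @param segment_seconds Length range of burst segments, in seconds.
#' @param p_active Probability that a segment is active (default 0.5).
#' @param seed Integer seed; identical seeds give identical profiles.
#' @return A tibble with columns `frame` (1-based) and `displacement`,
#'   and attributes `fps`, `kind`, `seed`.
#' @export
movement_profile <- function(n_frames, kind = c("bursts", "constant", "random_walk"),
                             displacement = 2, max_displacement = 4, fps = 30,
                             segment_seconds = c(2, 6), p_active = 0.5,
                             seed = NULL) {
  kind <- match.arg(kind)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (displacement < 0 || max_displacement < 0) {
    stop("displacements must be nonnegative", call. = FALSE)
  }
  gen <- function() {
    switch(kind,
      constant = rep(displacement, n_frames),
      bursts = {
        d <- numeric(0)
        while (length(d) < n_frames) {
          len <- max(1L, round(stats::runif(1, segment_seconds[1L], segment_seconds[2L]) * fps))
          if (stats::runif(1) < p_active) {
            amp <- sample.int(max(1L, max_displacement), 1L)
            d <- c(d, sample.int(amp + 1L, len, replace = TRUE) - 1L)
          } else {
            d <- c(d, rep(0, len))
          }
        }
        d[seq_len(n_frames)]
      },
      random_walk = {
        steps <- sample(c(-1L, 0L, 1L), n_frames, replace = TRUE)
        w <- numeric(n_frames)
        cur <- 0
        for (i in seq_len(n_frames)) {
          cur <- min(max(cur + steps[i], 0), max_displacement)
          w[i] <- cur
        }
        w
      }
    )
  }
  d <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out <- tibble::tibble(frame = seq_len(n_frames), displacement = as.numeric(d))
  attr(out, "fps") <- fps
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  out
}

#' Scene configuration for synthetic video
#'
#' Describes the synthetic scene: a bright object (rectangle or ellipse)
#' translating horizontally over a quasi-static background with clamped
#' Gaussian pixel noise and optional slow uniform illumination drift. The
#' defaults keep the noise well below the engine's binary threshold, the
#' regime the threshold filter is designed for.
#'
#' @param width,height Frame size in pixels.
#' @param background Background intensity (8-bit units).
#' @param noise_sd SD of the per-pixel Gaussian background noise (8-bit
#'   units); frames are clamped to `[0, 255]`.
#' @param object Object shape, `"rectangle"` or `"ellipse"`.
#' @param object_width,object_height Object size in pixels.
#' @param object_intensity Object intensity (8-bit units).
#' @param drift_per_s Uniform illumination drift in intensity units/second.
#' @param fps Frame rate.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(width = 64, height = 64, background = 60,
                         noise_sd = 3, object = c("rectangle", "ellipse"),
                         object_width = 12, object_height = 12,
                         object_intensity = 200, drift_per_s = 0, fps = 30) {
  object <- match.arg(object)
  cfg <- list(
    width = width, height = height, background = background,
    noise_sd = noise_sd, object = object,
    object_width = object_width, object_height = object_height,
    object_intensity = object_intensity, drift_per_s = drift_per_s, fps = fps
  )
  if (object_width > width || object_height > height ||
    object_width < 1 || object_height < 1) {
    stop(
      "object (", object_width, "x", object_height,
      ") does not fit inside the ", width, "x", height, " frame",
      call. = FALSE
    )
  }
  structure(cfg, class = "scene_config")
}

#' Sensor configuration for synthetic contact-sensor streams
#'
#' @param rate_hz Sampling rate in Hz (4 for a pressure pad, 30 for a depth
#'   tracker, 50 for an accelerometer are the typical rates emulated).
#' @param gain Multiplicative gain applied to the latent profile.
#' @param noise_sd SD of additive Gaussian sensor noise.
#' @param lag_s Sensor lag in seconds (positive: the sensor trails the
#'   video).
#' @param channels `"scalar"`, `"tri_axis"`, or `"grid"`.
#' @param grid_nrow,grid_ncol Grid dimensions for `channels = "grid"`
#'   (default 38 x 41, a seat/back pressure pad).
#' @return A list of class `"sensor_config"`.
#' @export
sensor_config <- function(rate_hz = 4, gain = 1, noise_sd = 0.5, lag_s = 0,
                          channels = c("scalar", "tri_axis", "grid"),
                          grid_nrow = 38, grid_ncol = 41) {
  channels <- match.arg(channels)
  if (rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  structure(
    list(
      rate_hz = rate_hz, gain = gain, noise_sd = noise_sd, lag_s = lag_s,
      channels = channels, grid_nrow = grid_nrow, grid_ncol = grid_ncol
    ),
    class = "sensor_config"
  )
}

#' Generate a synthetic video from a movement profile
#'
#' Renders the scene frame by frame: the object translates horizontally by
#' the profile's displacement, bouncing off the frame edges; the background
#' is `background + drift` plus clamped Gaussian noise. Alongside the frames,
#' the exact per-frame count of pixels whose noise-free, drift-free intensity
#' changed (vacated plus newly occupied object pixels) is returned as ground
#' truth. Identical seeds give bit-identical output.
#'
#' @param profile A [movement_profile()] tibble.
#' @param scene A [scene_config()].
#' @param seed Integer seed for the pixel noise, or `NULL` to use the
#'   current RNG state.
#' @return A list with `frames` (a `height x width x n` grayscale array of
#'   8-bit intensities), `fps`, and `truth` — a tibble with `frame`
#'   (numbering matching [process_video()] samples: frame `i` compares video
#'   frames `i` and `i + 1`) and `changed_pixels`.
#' @export
generate_motion_video <- function(profile, scene = scene_config(), seed = NULL) {
  stopifnot(inherits(scene, "scene_config"))
  disp <- profile$displacement
  n <- length(disp) # frames
  w <- scene$width
  h <- scene$height
  ow <- scene$object_width
  oh <- scene$object_height

  mask <- object_mask(scene)
  top <- max(1L, (h - oh) %/% 2L + 1L)

  # bouncing horizontal trajectory of the object's left edge
  xmin <- 1
  xmax <- w - ow + 1
  if (xmax < xmin) stop("object does not fit inside the frame", call. = FALSE)
  if (xmax == xmin && any(disp > 0)) {
    stop("object fills the frame width and cannot move without leaving it",
      call. = FALSE
    )
  }
  x <- numeric(n)
  pos <- xmin
  dir <- 1
  for (i in seq_len(n)) {
    if (i > 1L) {
      pos <- pos + dir * disp[i]
      while (pos > xmax || pos < xmin) { # reflect at the edges
        if (pos > xmax) pos <- 2 * xmax - pos
        if (pos < xmin) pos <- 2 * xmin - pos
        dir <- -dir
      }
    }
    x[i] <- round(pos)
  }

  clean <- function(i) { # noise-free, drift-free scene
    f <- matrix(scene$background, h, w)
    cols <- x[i]:(x[i] + ow - 1L)
    rows <- top:(top + oh - 1L)
    block <- f[rows, cols]
    block[mask] <- scene$object_intensity
    f[rows, cols] <- block
    f
  }

  render <- function() {
    frames <- array(0L, dim = c(h, w, n))
    changed <- integer(max(n - 1L, 0L))
    prev <- NULL
    for (i in seq_len(n)) {
      base <- clean(i)
      if (i > 1L) changed[i - 1L] <- sum(base != prev)
      prev <- base
      f <- base + (i - 1L) / scene$fps * scene$drift_per_s
      if (scene$noise_sd > 0) {
        f <- f + stats::rnorm(h * w, 0, scene$noise_sd)
      }
      f <- floor(f + 0.5)
      f[f < 0] <- 0
      f[f > 255] <- 255
      frames[, , i] <- as.integer(f)
    }
    list(frames = frames, changed = changed)
  }
  res <- if (is.null(seed)) render() else withr::with_seed(seed, render())

  list(
    frames = res$frames,
    fps = scene$fps,
    truth = tibble::tibble(
      frame = seq_len(max(n - 1L, 0L)),
      changed_pixels = res$changed
    )
  )
}

object_mask <- function(scene) {
  ow <- scene$object_width
  oh <- scene$object_height
  if (scene$object == "rectangle") {
    matrix(TRUE, oh, ow)
  } else {
    r <- (row(matrix(0, oh, ow)) - (oh + 1) / 2) / (oh / 2)
    c_ <- (col(matrix(0, oh, ow)) - (ow + 1) / 2) / (ow / 2)
    r^2 + c_^2 <= 1
  }
}

#' Generate a synthetic sensor stream from a movement profile
#'
#' Resamples the latent profile to the sensor rate by integration: sample
#' `i` is the mean displacement over the video frames whose midpoints fall
#' in its sampling interval (shifted by `lag_s`; intervals outside the
#' profile read 0, and an interval shorter than a frame falls back to point
#' sampling). Contact sensors integrate the motion over their sampling
#' period rather than reading instantaneous frame-level jitter, and point
#' sampling a 30 fps signal at 4 Hz would alias. Gain is applied and
#' Gaussian noise added per channel. Channel layouts:
#'
#' * `"scalar"` — one magnitude channel, `gain * profile + noise`; emulates a
#'   mean-pressure or movement-magnitude stream.
#' * `"tri_axis"` — the signal is split over three axes along a fixed unit
#'   vector so that with zero noise the Euclidean norm recovers
#'   `gain * profile` exactly; each axis gets independent noise.
#' * `"grid"` — an `R x C` pressure-pad frame per sample; a load proportional
#'   to the profile is spread over a central patch so that [mean_grid()]
#'   recovers `gain * profile`; pressures are clamped at 0.
#'
#' @param profile A [movement_profile()] tibble.
#' @param sensor A [sensor_config()].
#' @param seed Integer seed for the sensor noise, or `NULL`.
#' @return For `"scalar"`: a tibble `timestamp_ms,value`; for `"tri_axis"`:
#'   a tibble `timestamp_ms,x,y,z`; for `"grid"`: a list with `frames`
#'   (`R x C x m` array), `timestamp_ms`, `rate_hz`.
#' @export
generate_sensor_series <- function(profile, sensor = sensor_config(), seed = NULL) {
  stopifnot(inherits(sensor, "sensor_config"))
  fps <- attr(profile, "fps")
  if (is.null(fps)) fps <- 30
  disp <- profile$displacement
  nf <- length(disp)
  duration <- nf / fps
  m <- round(duration * sensor$rate_hz)
  t_s <- (seq_len(m) - 1L) / sensor$rate_hz
  # partition frames over sensor intervals by frame midpoint, then average
  mid <- (seq_len(nf) - 0.5) / fps
  iv <- floor((mid + sensor$lag_s) * sensor$rate_hz) + 1L
  agg <- tapply(disp, factor(iv, levels = seq_len(m)), mean)
  # intervals shorter than a frame (rate_hz > fps) fall back to point sampling
  ctr <- (t_s + 0.5 / sensor$rate_hz) - sensor$lag_s
  src <- floor(ctr * fps) + 1L
  point <- ifelse(src >= 1L & src <= nf, disp[pmax(pmin(src, nf), 1L)], 0)
  latent <- ifelse(is.na(agg), point, agg)
  signal <- sensor$gain * as.numeric(latent)

  gen <- function() {
    switch(sensor$channels,
      scalar = tibble::tibble(
        timestamp_ms = t_s * 1000,
        value = signal + stats::rnorm(m, 0, sensor$noise_sd)
      ),
      tri_axis = {
        u <- c(1, 2, 2) / 3 # fixed unit direction
        tibble::tibble(
          timestamp_ms = t_s * 1000,
          x = signal * u[1L] + stats::rnorm(m, 0, sensor$noise_sd),
          y = signal * u[2L] + stats::rnorm(m, 0, sensor$noise_sd),
          z = signal * u[3L] + stats::rnorm(m, 0, sensor$noise_sd)
        )
      },
      grid = {
        r <- sensor$grid_nrow
        c_ <- sensor$grid_ncol
        pr <- max(1L, r %/% 2L)
        pc <- max(1L, c_ %/% 2L)
        r0 <- (r - pr) %/% 2L
        c0 <- (c_ - pc) %/% 2L
        frames <- array(0, dim = c(r, c_, m))
        for (i in seq_len(m)) {
          f <- matrix(0, r, c_)
          f[(r0 + 1L):(r0 + pr), (c0 + 1L):(c0 + pc)] <-
            signal[i] * (r * c_) / (pr * pc)
          if (sensor$noise_sd > 0) {
            f <- f + stats::rnorm(r * c_, 0, sensor$noise_sd)
          }
          frames[, , i] <- pmax(f, 0) # pressures are nonnegative
        }
        list(frames = frames, timestamp_ms = t_s * 1000, rate_hz = sensor$rate_hz)
      }
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate and write a complete paired fixture
#'
#' Builds a movement profile, the synthetic video, and a co-registered
#' sensor stream, and writes them to `out_dir`: `video.avi` (uncompressed),
#' `sensor.csv` (or `sensor.grid` for a pressure pad), `truth.csv`, and a
#' plain-text `manifest.txt` recording every parameter and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param duration_s Video duration in seconds.
#' @param scene A [scene_config()].
#' @param sensor A [sensor_config()].
#' @param kind Movement-profile kind.
#' @param seed Integer seed governing profile, pixel noise and sensor noise.
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`profile`, `video`, `sensor`).
#' @export
simulate_fixture <- function(out_dir, duration_s = 60, scene = scene_config(),
                             sensor = sensor_config(), kind = "bursts",
                             seed = 1) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_frames <- round(duration_s * scene$fps)
  if (n_frames < 2) stop("duration too short: fewer than 2 frames", call. = FALSE)
  profile <- movement_profile(n_frames, kind = kind, fps = scene$fps, seed = seed)
  video <- generate_motion_video(profile, scene, seed = seed + 1L)
  sens <- generate_sensor_series(profile, sensor, seed = seed + 2L)

  video_path <- file.path(out_dir, "video.avi")
  write_avi(video$frames, video_path, fps = scene$fps)
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(video$truth, truth_path)
  if (sensor$channels == "grid") {
    sensor_path <- file.path(out_dir, "sensor.grid")
    write_pressure_grid(sens$frames, sensor_path, rate_hz = sensor$rate_hz)
  } else {
    sensor_path <- file.path(out_dir, "sensor.csv")
    write_series_csv(sens, sensor_path)
  }

  manifest <- c(
    sprintf("kind=%s", kind),
    sprintf("seed=%d", seed),
    sprintf("duration_s=%g", duration_s),
    sprintf("fps=%g", scene$fps),
    sprintf("width=%d", scene$width),
    sprintf("height=%d", scene$height),
    sprintf("background=%g", scene$background),
    sprintf("noise_sd=%g", scene$noise_sd),
    sprintf("object=%s", scene$object),
    sprintf("object_width=%d", scene$object_width),
    sprintf("object_height=%d", scene$object_height),
    sprintf("object_intensity=%g", scene$object_intensity),
    sprintf("drift_per_s=%g", scene$drift_per_s),
    sprintf("sensor_rate_hz=%g", sensor$rate_hz),
    sprintf("sensor_gain=%g", sensor$gain),
    sprintf("sensor_noise_sd=%g", sensor$noise_sd),
    sprintf("sensor_lag_s=%g", sensor$lag_s),
    sprintf("sensor_channels=%s", sensor$channels)
  )
  manifest_path <- file.path(out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)

  invisible(list(
    video = video_path, sensor = sensor_path, truth = truth_path,
    manifest = manifest_path,
    objects = list(profile = profile, video = video, sensor = sens)
  ))
}
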