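#' Tracker configuration
#'
#' Holds the two parameters of the silhouette engine plus an optional frame
#' rate override. The defaults `N = 1000` ms and `T = 30` are the values that
#' work well for tracking torso/face or full-body movement under ordinary
#' indoor lighting: `N` is the MHI memory (momentum smoothing; motion older
#' than `N` ms is forgotten) and `T` is the binary threshold that filters
#' background noise such as lighting flicker out of the frame difference.
#'
#' @param mhi_duration_ms MHI memory `N` in milliseconds; must be > 0.
#' @param threshold Binary threshold `T`, an 8-bit intensity in `[0, 255]`.
#' @param fps_override Frames per second to use instead of (or in the absence
#'   of) the container's frame rate, or `NULL`.
#' @return A list of class `"tracker_config"`.
#' @export
tracker_config <- function(mhi_duration_ms = 1000, threshold = 30,
                           fps_override = NULL) {
  if (!is.numeric(mhi_duration_ms) || mhi_duration_ms <= 0) {
    stop("mhi_duration_ms must be > 0", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255) {
    stop("threshold must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(
      mhi_duration_ms = mhi_duration_ms,
      threshold = threshold,
      fps_override = fps_override
    ),
    class = "tracker_config"
  )
}

#' Estimate per-frame body movement from a video
#'
#' Runs the silhouette engine over a video: each frame is converted to
#' grayscale, differenced against its predecessor, thresholded into a binary
#' silhouette, folded into the motion history image, and summarised as the
#' motion index (fraction of pixels with motion inside the MHI memory).
#' Timestamps are derived from the frame index and the frame rate, never from
#' a wall clock, so repeated runs are bit-identical.
#'
#' The first frame has no predecessor and emits no sample; the series starts
#' at the second frame with `frame = 1` (frames are numbered from 0) and
#' `timestamp_ms = frame * 1000 / fps`.
#'
#' @param video One of: a path to an uncompressed AVI file, a path to a
#'   directory of PNG frames (sorted by file name; requires
#'   `fps_override`), a `height x width x n` grayscale array, a
#'   `height x width x 3 x n` RGB array, a list of frames, or the
#'   `list(frames =, fps =)` value returned by [read_avi()] or
#'   [generate_motion_video()].
#' @param config A [tracker_config()].
#' @param export_dir If non-`NULL`, a directory into which per-frame PNGs of
#'   the binary silhouette (`sil_%05d.png`) and rendered MHI
#'   (`mhi_%05d.png`) are written.
#' @param export Which images to export: `"silhouette"`, `"mhi"`, or both.
#' @return A tibble of class `"motion_series"` with columns `frame`,
#'   `timestamp_ms`, `motion_index`, one row per frame starting at the
#'   second; attributes `fps` and `config`.
#' @examples
#' vid <- array(0, dim = c(8, 8, 3)) # three identical black frames
#' process_video(vid, tracker_config(fps_override = 30))
#' @export
process_video <- function(video, config = tracker_config(),
                          export_dir = NULL,
                          export = c("silhouette", "mhi")) {
  stopifnot(inherits(config, "tracker_config"))
  loaded <- load_video(video, config$fps_override)
  frames <- loaded$frames
  fps <- loaded$fps
  if (is.null(fps) || !is.numeric(fps) || fps <= 0) {
    stop(
      "frame rate is zero or unknown; supply tracker_config(fps_override = )",
      call. = FALSE
    )
  }
  n <- length(frames)
  if (n < 2L) {
    stop("video must contain at least 2 frames, got ", n, call. = FALSE)
  }
  d <- frame_dims(frames[[1L]])
  export <- if (is.null(export_dir)) character() else match.arg(export, several.ok = TRUE)
  if (!is.null(export_dir) && !dir.exists(export_dir)) {
    dir.create(export_dir, recursive = TRUE)
  }

  g_prev <- convert_grayscale(frames[[1L]])
  mhi <- mhi_create(d[2L], d[1L], config$mhi_duration_ms)
  idx <- numeric(n - 1L)
  for (i in 2:n) {
    if (!identical(frame_dims(frames[[i]]), d)) {
      stop(
        "frame size changed mid-stream at frame ", i - 1L, ": ",
        paste(d, collapse = "x"), " -> ",
        paste(frame_dims(frames[[i]]), collapse = "x"),
        call. = FALSE
      )
    }
    g <- convert_grayscale(frames[[i]])
    sil <- binarize(frame_difference(g, g_prev), config$threshold)
    t_now <- (i - 1L) * 1000 / fps
    mhi <- mhi_update(mhi, sil, t_now)
    idx[i - 1L] <- motion_index(mhi)
    if ("silhouette" %in% export) {
      png::writePNG(
        matrix(as.numeric(sil), nrow(sil), ncol(sil)),
        file.path(export_dir, sprintf("sil_%05d.png", i - 1L))
      )
    }
    if ("mhi" %in% export) {
      png::writePNG(
        mhi_render(mhi, t_now) / 255,
        file.path(export_dir, sprintf("mhi_%05d.png", i - 1L))
      )
    }
    g_prev <- g
  }
  out <- tibble::tibble(
    frame = seq_len(n - 1L),
    timestamp_ms = seq_len(n - 1L) * 1000 / fps,
    motion_index = idx
  )
  attr(out, "fps") <- fps
  attr(out, "config") <- config
  class(out) <- c("motion_series", class(out))
  out
}

load_video <- function(video, fps_override = NULL) {
  fps <- fps_override
  if (is.character(video)) {
    stopifnot(length(video) == 1L)
    if (dir.exists(video)) {
      paths <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
      if (length(paths) == 0L) {
        stop("no PNG frames found in directory ", video, call. = FALSE)
      }
      frames <- lapply(paths, read_png_frame)
    } else {
      avi <- read_avi(video)
      frames <- as_frame_list(avi$frames)
      if (is.null(fps)) fps <- avi$fps
    }
  } else if (is.list(video) && !is.null(video$frames)) {
    frames <- as_frame_list(video$frames)
    if (is.null(fps)) fps <- video$fps
  } else {
    frames <- as_frame_list(video)
  }
  list(frames = frames, fps = fps)
}

read_png_frame <- function(path) {
  img <- png::readPNG(path) * 255
  if (length(dim(img)) == 3L && dim(img)[3L] %in% c(2L, 4L)) {
    img <- img[, , -dim(img)[3L], drop = FALSE] # drop alpha
  }
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img
}

#' Write / read a motion-index series as CSV
#'
#' The on-disk format is the per-frame text output of the tracker: a header
#' `frame,timestamp_ms,motion_index` and one row per emitted sample, with
#' missing values written as empty fields.
#'
#' @param series A tibble with columns `frame`, `timestamp_ms`,
#'   `motion_index` (as returned by [process_video()]).
#' @param path File path.
#' @return `write_motion_csv()` returns `path` invisibly; `read_motion_csv()`
#'   returns a `motion_series` tibble.
#' @export
write_motion_csv <- function(series, path) {
  stopifnot(all(c("frame", "timestamp_ms", "motion_index") %in% names(series)))
  readr::write_csv(
    series[, c("frame", "timestamp_ms", "motion_index")],
    path,
    na = ""
  )
  invisible(path)
}

#' @rdname write_motion_csv
#' @export
read_motion_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      frame = readr::col_integer(),
      timestamp_ms = readr::col_double(),
      motion_index = readr::col_double()
    ),
    na = ""
  )
  class(out) <- c("motion_series", class(out))
  out
}
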