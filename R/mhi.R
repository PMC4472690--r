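#' Motion history image
#'
#' A motion history image (MHI) records, per pixel, the most recent time (in
#' milliseconds) at which motion was observed there; 0 means no motion inside
#' the memory window. Entries older than the memory duration `N` are expired
#' at each update, so the MHI acts as a rolling background model: the set of
#' nonzero cells is "everything that moved within the last `N` ms".
#'
#' Internally the MHI stores raw timestamps rather than a decaying-brightness
#' image; [mhi_render()] produces the familiar fading-intensity picture as an
#' affine map of timestamp age.
#'
#' @param width,height Frame dimensions in pixels.
#' @param duration_ms Memory length `N` in milliseconds (default 1000).
#' @return An object of class `"mhi"`: a list with elements `timestamps`
#'   (a `height x width` numeric matrix of ms, 0 = inactive), `duration_ms`,
#'   and `t_now` (the clock after the last update, `-Inf` before any).
#' @seealso [mhi_update()], [motion_index()], [mhi_render()]
#' @export
mhi_create <- function(width, height, duration_ms = 1000) {
  stopifnot(width >= 1, height >= 1)
  if (!is.numeric(duration_ms) || duration_ms <= 0) {
    stop("duration_ms (the MHI memory N) must be > 0", call. = FALSE)
  }
  structure(
    list(
      timestamps = matrix(0, nrow = height, ncol = width),
      duration_ms = duration_ms,
      t_now = -Inf
    ),
    class = "mhi"
  )
}

#' Update a motion history image with a binary silhouette
#'
#' Foreground pixels are stamped with the current time; background pixels
#' whose stored timestamp has aged beyond the memory duration
#' (`timestamp < t_now - N`) are reset to 0; all other pixels keep their
#' stored timestamp. A timestamp exactly `N` ms old is retained.
#'
#' @param mhi An [mhi_create()] object.
#' @param silhouette A logical matrix (foreground = `TRUE`) with the same
#'   dimensions as the MHI.
#' @param t_now Current timestamp in milliseconds; must not move backwards.
#' @return The updated `"mhi"` object.
#' @export
mhi_update <- function(mhi, silhouette, t_now) {
  stopifnot(inherits(mhi, "mhi"))
  if (!identical(dim(silhouette), dim(mhi$timestamps))) {
    stop(
      "silhouette dimensions ", paste(dim(silhouette), collapse = "x"),
      " do not match MHI dimensions ",
      paste(dim(mhi$timestamps), collapse = "x"),
      call. = FALSE
    )
  }
  if (t_now < mhi$t_now) {
    stop(
      "non-monotonic clock: t_now = ", t_now,
      " is earlier than the last update at ", mhi$t_now,
      call. = FALSE
    )
  }
  ts <- mhi$timestamps
  ts[silhouette] <- t_now
  expired <- !silhouette & ts != 0 & ts < t_now - mhi$duration_ms
  ts[expired] <- 0
  mhi$timestamps <- ts
  mhi$t_now <- t_now
  mhi
}

#' Motion index: proportion of pixels with recorded motion
#'
#' The fraction of MHI cells holding a nonzero timestamp, i.e. the proportion
#' of the frame displaced within the memory window. This is the method's
#' single per-frame measure of general body movement: 10 active pixels in a
#' 10 x 10 frame give an index of 10/100 = 0.1.
#'
#' @param mhi An [mhi_create()] object.
#' @return A fraction in `[0, 1]`.
#' @export
motion_index <- function(mhi) {
  stopifnot(inherits(mhi, "mhi"))
  ts <- mhi$timestamps
  if (length(ts) == 0L) stop("empty MHI", call. = FALSE)
  sum(ts != 0) / length(ts)
}

#' Render a motion history image as an 8-bit intensity grid
#'
#' Maps timestamp age to brightness: the most recent motion is maximal
#' brightness (255) and intensity falls off linearly to 0 at age `N`,
#' reproducing the classic decaying-silhouette visualisation.
#'
#' @param mhi An [mhi_create()] object.
#' @param t_now Reference time in ms; defaults to the MHI's own clock.
#' @return An integer matrix in `[0, 255]`.
#' @export
mhi_render <- function(mhi, t_now = mhi$t_now) {
  stopifnot(inherits(mhi, "mhi"))
  ts <- mhi$timestamps
  age <- (t_now - ts) / mhi$duration_ms
  bright <- pmax(0, 1 - age) * 255
  bright[ts == 0] <- 0
  matrix(as.integer(floor(bright + 0.5)), nrow(ts), ncol(ts))
}

#' @export
print.mhi <- function(x, ...) {
  d <- dim(x$timestamps)
  cat(
    "<motion history image> ", d[2L], "x", d[1L],
    " px, N = ", x$duration_ms, " ms, ",
    sum(x$timestamps != 0), " active pixel(s), t = ",
    if (is.finite(x$t_now)) paste0(x$t_now, " ms") else "unset", "\n",
    sep = ""
  )
  invisible(x)
}
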