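#' Convert a video frame to 8-bit grayscale
#'
#' Collapses an RGB frame to a single luma channel using the BT.601 weights
#' (0.299, 0.587, 0.114), the standard-definition luma transform used
#' throughout video processing. Values are rounded half-up to the nearest
#' integer so the result is again an 8-bit intensity grid. A frame that is
#' already grayscale (a plain matrix, or an array with one channel) passes
#' through unchanged.
#'
#' @param frame A `height x width` numeric matrix of intensities in
#'   `[0, 255]`, or a `height x width x 3` array of RGB channel values.
#'   Inputs with more than 8-bit depth (values above 255) are linearly
#'   rescaled to `[0, 255]` before conversion.
#' @return A `height x width` integer matrix of intensities in `[0, 255]`.
#' @examples
#' rgb <- array(0, dim = c(2, 2, 3))
#' rgb[1, 1, 1] <- 255 # pure red
#' convert_grayscale(rgb)[1, 1] # 76
#' @export
convert_grayscale <- function(frame) {
  if (is.null(frame) || length(frame) == 0L) {
    stop("empty frame: cannot convert a frame with no pixels", call. = FALSE)
  }
  if (is.matrix(frame)) {
    gray <- frame
  } else if (is.array(frame) && length(dim(frame)) == 3L) {
    nc <- dim(frame)[3L]
    if (nc == 1L) {
      gray <- frame[, , 1L, drop = FALSE]
    } else if (nc >= 3L) {
      gray <- 0.299 * frame[, , 1L, drop = FALSE] +
        0.587 * frame[, , 2L, drop = FALSE] +
        0.114 * frame[, , 3L, drop = FALSE]
    } else {
      stop("frame must have 1 or 3 channels, got ", nc, call. = FALSE)
    }
  } else {
    stop("frame must be a matrix or a height x width x channels array",
      call. = FALSE
    )
  }
  if (any(gray < 0, na.rm = TRUE)) {
    stop("negative intensities are not valid 8-bit pixel values", call. = FALSE)
  }
  dim(gray) <- dim(frame)[1:2] # guard against dropped singleton dimensions
  mx <- max(gray)
  if (mx > 255) gray <- gray / mx * 255 # deeper-than-8-bit input
  matrix(as.integer(floor(gray + 0.5)), nrow(gray), ncol(gray))
}

#' Absolute difference of two grayscale frames
#'
#' The per-pixel absolute intensity difference `|curr - prev|`, the raw motion
#' silhouette before thresholding.
#'
#' @param curr,prev Two grayscale frames (integer matrices) of identical
#'   dimensions.
#' @return An integer matrix of the same dimensions with values in `[0, 255]`.
#' @export
frame_difference <- function(curr, prev) {
  if (!identical(dim(curr), dim(prev))) {
    stop(
      "frame dimensions differ: ", paste(dim(curr), collapse = "x"),
      " vs ", paste(dim(prev), collapse = "x"),
      call. = FALSE
    )
  }
  abs(curr - prev)
}

#' Threshold a difference image into a binary silhouette
#'
#' A pixel is foreground iff its difference value strictly exceeds the
#' threshold `T`. The strict inequality means `threshold = 0` marks exactly
#' the nonzero-difference pixels, and uniform intensity shifts of at most `T`
#' between consecutive frames are filtered out entirely.
#'
#' @param diff An integer matrix of absolute frame differences.
#' @param threshold The binary threshold `T`, an intensity in `[0, 255]`
#'   (default 30).
#' @return A logical matrix: `TRUE` where motion exceeded the threshold.
#' @export
binarize <- function(diff, threshold = 30) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold < 0 || threshold > 255) {
    stop("threshold must lie in [0, 255], got ", threshold, call. = FALSE)
  }
  diff > threshold
}
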