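# Minimal RIFF AVI container support for uncompressed ("DIB ") 24-bit video.
# Only the profile written by write_avi() is guaranteed to round-trip; any
# compressed stream is rejected with a clear error. All multi-byte fields are
# little-endian per the RIFF specification.

AVI_HDRL_BYTES <- 192L # avih chunk + one video strl list

#' Write frames to an uncompressed AVI file
#'
#' Writes a fixed-size, fixed-rate video as an uncompressed 24-bit RGB
#' ("DIB ") AVI, the simplest widely readable video container. Grayscale
#' frames are replicated across the three channels. The file carries a
#' standard `idx1` index so mainstream players accept it.
#'
#' @param frames A `height x width x n` array of grayscale intensities in
#'   `[0, 255]`, a `height x width x 3 x n` RGB array, or a list of frames
#'   (matrices or `height x width x 3` arrays) of constant size.
#' @param path Output file path.
#' @param fps Frames per second (stored as a rational with ms precision).
#' @return `path`, invisibly.
#' @seealso [read_avi()]
#' @export
write_avi <- function(frames, path, fps = 30) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  fr <- as_frame_list(frames)
  n <- length(fr)
  if (n < 1L) stop("no frames to write", call. = FALSE)
  d <- frame_dims(fr[[1L]])
  h <- d[1L]
  w <- d[2L]
  for (i in seq_along(fr)) {
    if (!identical(frame_dims(fr[[i]]), d)) {
      stop("frame ", i, " has different dimensions; AVI frames must be constant size",
        call. = FALSE
      )
    }
  }
  rowbytes <- ((3L * w + 3L) %/% 4L) * 4L
  framebytes <- rowbytes * h

  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wcc <- function(s) writeBin(charToRaw(s), con)

  movi_bytes <- 4L + n * (8L + framebytes)
  idx_bytes <- 16L * n
  riff_bytes <- 4L + (8L + AVI_HDRL_BYTES) + (8L + movi_bytes) + (8L + idx_bytes)

  wcc("RIFF"); w4(riff_bytes); wcc("AVI ")

  # ---- header list -------------------------------------------------------
  wcc("LIST"); w4(AVI_HDRL_BYTES); wcc("hdrl")
  wcc("avih"); w4(56L)
  w4(round(1e6 / fps)) # dwMicroSecPerFrame
  w4(framebytes * ceiling(fps)) # dwMaxBytesPerSec
  w4(0L) # dwPaddingGranularity
  w4(16L) # dwFlags: AVIF_HASINDEX
  w4(n) # dwTotalFrames
  w4(0L) # dwInitialFrames
  w4(1L) # dwStreams
  w4(framebytes) # dwSuggestedBufferSize
  w4(w); w4(h)
  w4(rep(0L, 4L)) # dwReserved

  wcc("LIST"); w4(116L); wcc("strl")
  wcc("strh"); w4(56L)
  wcc("vids"); wcc("DIB ")
  w4(0L) # dwFlags
  w2(0L); w2(0L) # wPriority, wLanguage
  w4(0L) # dwInitialFrames
  w4(1000L) # dwScale
  w4(round(fps * 1000)) # dwRate -> fps = rate/scale
  w4(0L) # dwStart
  w4(n) # dwLength
  w4(framebytes) # dwSuggestedBufferSize
  w4(0L) # dwQuality
  w4(0L) # dwSampleSize
  w2(0L); w2(0L); w2(w); w2(h) # rcFrame

  wcc("strf"); w4(40L)
  w4(40L) # biSize
  w4(w); w4(h) # positive height = bottom-up rows
  w2(1L); w2(24L) # biPlanes, biBitCount
  w4(0L) # biCompression = BI_RGB (uncompressed)
  w4(framebytes) # biSizeImage
  w4(rep(0L, 4L)) # pels/meter, clr fields

  # ---- frame data --------------------------------------------------------
  wcc("LIST"); w4(movi_bytes); wcc("movi")
  for (i in seq_len(n)) {
    wcc("00db"); w4(framebytes)
    writeBin(frame_to_dib(fr[[i]], rowbytes), con)
  }

  # ---- idx1 index --------------------------------------------------------
  wcc("idx1"); w4(idx_bytes)
  for (i in seq_len(n)) {
    wcc("00db")
    w4(16L) # AVIIF_KEYFRAME
    w4(4L + (i - 1L) * (8L + framebytes)) # offset from 'movi' fourcc
    w4(framebytes)
  }
  invisible(path)
}

#' Read an uncompressed AVI file
#'
#' Parses the RIFF chunk tree, validates that the single video stream is
#' uncompressed 24-bit RGB, and decodes every frame. Compressed AVI (or any
#' other codec) is rejected: decoding arbitrary codecs is out of scope.
#'
#' @param path Path to an AVI file.
#' @return A list with `frames` (a `height x width x n` grayscale array when
#'   all three channels agree, otherwise a `height x width x 3 x n` RGB
#'   array) and `fps` (frames per second from the stream header).
#' @export
read_avi <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read video: file does not exist: ", path, call. = FALSE)
  }
  size <- file.size(path)
  if (is.na(size) || size < 24) {
    stop("cannot read video: not a RIFF AVI file: ", path, call. = FALSE)
  }
  r <- readBin(path, "raw", size)
  cc <- function(at) rawToChar(r[at:(at + 3L)])
  u32 <- function(at) {
    v <- readBin(r[at:(at + 3L)], "integer", size = 4L, endian = "little")
    if (v < 0) stop("chunk size overflows 31 bits; file too large", call. = FALSE)
    v
  }
  u16 <- function(at) {
    readBin(r[at:(at + 1L)], "integer", size = 2L, signed = FALSE, endian = "little")
  }
  if (cc(1L) != "RIFF" || cc(9L) != "AVI ") {
    stop("cannot read video: not a RIFF AVI file: ", path, call. = FALSE)
  }

  found <- new.env(parent = emptyenv())
  found$chunks <- list()
  walk <- function(at, end) {
    while (at + 7L <= end) {
      id <- cc(at)
      sz <- u32(at + 4L)
      if (id == "LIST") {
        walk(at + 12L, min(end, at + 8L + sz))
      } else {
        found$chunks[[length(found$chunks) + 1L]] <-
          list(id = id, at = at + 8L, size = sz)
      }
      at <- at + 8L + sz + (sz %% 2L)
    }
  }
  walk(13L, min(size, 8L + u32(5L)))

  ids <- vapply(found$chunks, `[[`, "", "id")
  strh <- found$chunks[[match("strh", ids)]]
  strf <- found$chunks[[match("strf", ids)]]
  avih <- found$chunks[[match("avih", ids)]]
  if (anyNA(match(c("strh", "strf", "avih"), ids))) {
    stop("cannot read video: missing AVI stream headers in ", path, call. = FALSE)
  }

  scale <- u32(strh$at + 20L)
  rate <- u32(strh$at + 24L)
  fps <- if (scale > 0 && rate > 0) rate / scale else {
    usec <- u32(avih$at)
    if (usec > 0) 1e6 / usec else 0
  }

  w <- u32(strf$at + 4L)
  h0 <- readBin(r[(strf$at + 8L):(strf$at + 11L)], "integer",
    size = 4L, endian = "little"
  )
  h <- abs(h0)
  bottom_up <- h0 > 0
  bits <- u16(strf$at + 14L)
  compression <- u32(strf$at + 16L)
  if (compression != 0L || bits != 24L) {
    stop(
      "unsupported AVI codec in ", path,
      ": only uncompressed 24-bit RGB ('DIB ') streams are supported",
      call. = FALSE
    )
  }

  rowbytes <- ((3L * w + 3L) %/% 4L) * 4L
  vids <- found$chunks[ids %in% c("00db", "00dc")]
  if (length(vids) == 0L) {
    stop("cannot read video: no frame data in ", path, call. = FALSE)
  }
  frames <- array(0L, dim = c(h, w, 3L, length(vids)))
  for (i in seq_along(vids)) {
    ch <- vids[[i]]
    if (ch$size < rowbytes * h) {
      stop("cannot read video: truncated frame ", i, " in ", path, call. = FALSE)
    }
    frames[, , , i] <- dib_to_frame(
      r[ch$at:(ch$at + rowbytes * h - 1L)], w, h, bottom_up
    )
  }
  if (all(frames[, , 1L, ] == frames[, , 2L, ]) &&
    all(frames[, , 1L, ] == frames[, , 3L, ])) {
    frames <- frames[, , 1L, , drop = TRUE]
    dim(frames) <- c(h, w, length(vids)) # keep 3-D even for a single frame
  }
  list(frames = frames, fps = fps)
}

# ---- helpers -------------------------------------------------------------

as_frame_list <- function(frames) {
  if (is.list(frames)) {
    return(frames)
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    return(lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i]))
  }
  if (is.array(frames) && length(dim(frames)) == 4L) {
    return(lapply(seq_len(dim(frames)[4L]), function(i) frames[, , , i]))
  }
  if (is.matrix(frames)) {
    return(list(frames))
  }
  stop("frames must be a 3-D/4-D array or a list of frames", call. = FALSE)
}

frame_dims <- function(f) dim(f)[1:2]

# Pack one frame as a bottom-up BGR DIB payload with 4-byte row alignment.
frame_to_dib <- function(f, rowbytes) {
  if (is.matrix(f)) {
    rch <- gch <- bch <- f
  } else {
    rch <- f[, , 1L]
    gch <- f[, , 2L]
    bch <- f[, , 3L]
  }
  h <- nrow(rch)
  w <- ncol(rch)
  clamp8 <- function(m) {
    m <- floor(m + 0.5)
    m[m < 0] <- 0
    m[m > 255] <- 255
    m
  }
  ord <- h:1
  core <- array(0L, dim = c(3L, w, h))
  core[1L, , ] <- t(clamp8(bch)[ord, , drop = FALSE])
  core[2L, , ] <- t(clamp8(gch)[ord, , drop = FALSE])
  core[3L, , ] <- t(clamp8(rch)[ord, , drop = FALSE])
  m <- matrix(as.integer(core), nrow = 3L * w, ncol = h)
  if (rowbytes > 3L * w) {
    m <- rbind(m, matrix(0L, rowbytes - 3L * w, h))
  }
  as.raw(m)
}

dib_to_frame <- function(bytes, w, h, bottom_up = TRUE) {
  rowbytes <- ((3L * w + 3L) %/% 4L) * 4L
  m <- matrix(as.integer(bytes), nrow = rowbytes)[seq_len(3L * w), , drop = FALSE]
  core <- array(m, dim = c(3L, w, h))
  ord <- if (bottom_up) h:1 else seq_len(h)
  out <- array(0L, dim = c(h, w, 3L))
  out[, , 1L] <- t(core[3L, , ])[ord, , drop = FALSE][seq_len(h), , drop = FALSE]
  out[, , 2L] <- t(core[2L, , ])[ord, , drop = FALSE][seq_len(h), , drop = FALSE]
  out[, , 3L] <- t(core[1L, , ])[ord, , drop = FALSE][seq_len(h), , drop = FALSE]
  out
}
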