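# Independent oracles and fixture builders, deliberately naive: plain loops
# over pixels and frames, no shared code with the package internals.

# Per-pixel reference implementation of the whole silhouette engine.
reference_motion_series <- function(frames, fps, duration_ms = 1000,
                                    threshold = 30) {
  gray <- lapply(frames, function(f) {
    if (is.matrix(f)) {
      g <- f
    } else {
      g <- matrix(0, dim(f)[1], dim(f)[2])
      for (r in seq_len(dim(f)[1])) {
        for (c in seq_len(dim(f)[2])) {
          g[r, c] <- floor(0.299 * f[r, c, 1] + 0.587 * f[r, c, 2] +
            0.114 * f[r, c, 3] + 0.5)
        }
      }
    }
    g
  })
  h <- nrow(gray[[1]])
  w <- ncol(gray[[1]])
  stamps <- matrix(0, h, w)
  idx <- numeric(length(frames) - 1)
  for (i in 2:length(frames)) {
    t_now <- (i - 1) * 1000 / fps
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if (abs(gray[[i]][r, c] - gray[[i - 1]][r, c]) > threshold) {
          stamps[r, c] <- t_now
        } else if (stamps[r, c] != 0 && stamps[r, c] < t_now - duration_ms) {
          stamps[r, c] <- 0
        }
      }
    }
    idx[i - 1] <- sum(stamps != 0) / (h * w)
  }
  idx
}

# A color video as a list of h x w x 3 arrays of random 8-bit values.
random_color_video <- function(h, w, n) {
  lapply(seq_len(n), function(i) {
    array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  })
}

# A grayscale video in which a k-pixel block alternates between two disjoint
# locations, so every frame difference marks exactly 2k pixels.
alternating_block_video <- function(n_frames, h = 16, w = 16, block = 3) {
  lapply(seq_len(n_frames), function(i) {
    f <- matrix(0, h, w)
    if (i %% 2 == 0) {
      f[1:block, 1:block] <- 255
    } else {
      f[(h - block + 1):h, (w - block + 1):w] <- 255
    }
    f
  })
}
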