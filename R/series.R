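# Preprocessing of movement time series (video-derived or contact-sensor).
# All functions are tibble-in / tibble-out; a bare numeric vector is accepted
# and wrapped as tibble(value = x). The value column is found automatically
# ("value", "motion_index", or "index") or named explicitly via `col`.

series_tbl <- function(data, col = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(value = as.numeric(data))
  }
  if (!is.data.frame(data)) {
    stop("data must be a data frame or a numeric vector", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (is.null(col)) {
    col <- intersect(c("value", "motion_index", "index"), names(data))[1L]
    if (is.na(col)) {
      stop(
        "no value column found (looked for 'value', 'motion_index', 'index'); ",
        "name one with col = ",
        call. = FALSE
      )
    }
  } else if (!col %in% names(data)) {
    stop("column '", col, "' not found in data", call. = FALSE)
  }
  list(data = data, col = col)
}

#' Discard the burn-in of a series
#'
#' Removes the initial span of a recording during which the rolling
#' background model is still stabilising. Either a fixed span is removed
#' (`burn_in_seconds`, converted to `round(burn_in_seconds * rate_hz)`
#' samples, or `burn_in_samples` directly), or, with `auto = TRUE`, the
#' maximal leading run of values above `mean + z_threshold * SD` of the full
#' series is removed — the "first few values are much higher than all those
#' following" heuristic.
#'
#' @param data A data frame with a value column, or a numeric vector.
#' @param rate_hz Sampling rate in Hz (needed to convert seconds to samples).
#' @param burn_in_seconds Span to discard, in seconds (default 1).
#' @param burn_in_samples Span to discard, in samples; overrides
#'   `burn_in_seconds`.
#' @param auto If `TRUE`, use the leading-outlier-run rule instead of a fixed
#'   span.
#' @param z_threshold SD-unit threshold for the auto rule (default 2.5).
#' @param col Name of the value column, or `NULL` to detect it.
#' @return The input tibble minus its leading rows.
#' @export
discard_burn_in <- function(data, rate_hz = NULL, burn_in_seconds = 1,
                            burn_in_samples = NULL, auto = FALSE,
                            z_threshold = 2.5, col = NULL) {
  s <- series_tbl(data, col)
  v <- s$data[[s$col]]
  n <- length(v)
  if (auto) {
    m <- mean(v, na.rm = TRUE)
    sd_ <- stats::sd(v, na.rm = TRUE)
    drop <- 0L
    if (is.finite(sd_) && sd_ > 0) {
      while (drop < n && !is.na(v[drop + 1L]) &&
        v[drop + 1L] > m + z_threshold * sd_) {
        drop <- drop + 1L
      }
    }
  } else if (!is.null(burn_in_samples)) {
    drop <- as.integer(burn_in_samples)
  } else {
    if (burn_in_seconds < 0) stop("burn_in_seconds must be >= 0", call. = FALSE)
    if (burn_in_seconds == 0) {
      drop <- 0L
    } else {
      if (is.null(rate_hz) || rate_hz <= 0) {
        stop("rate_hz is required to convert burn_in_seconds to samples",
          call. = FALSE
        )
      }
      drop <- as.integer(round(burn_in_seconds * rate_hz))
    }
  }
  if (drop < 0) stop("burn-in must be >= 0", call. = FALSE)
  if (drop >= n) {
    stop(
      "burn-in of ", drop, " samples would discard the whole series (length ",
      n, ")",
      call. = FALSE
    )
  }
  s$data[seq.int(drop + 1L, n), , drop = FALSE]
}

#' Flag and blank z-score outliers
#'
#' One-pass rule: the mean and (sample) SD are computed once over the
#' non-missing values, and every value more than `z_threshold` SDs from that
#' mean — in either direction — is set to missing. A constant series (SD = 0)
#' flags nothing. The pass is deliberately not iterated: re-applying the rule
#' after blanking changes the mean and SD and may flag more values.
#'
#' @param data A data frame with a value column, or a numeric vector.
#' @param z_threshold Flagging threshold in SD units (default 2.5).
#' @param col Name of the value column, or `NULL` to detect it.
#' @return The input tibble with flagged values set to `NA`, an added logical
#'   `outlier` column, and attribute `outlier_fraction` (flagged / non-missing
#'   values); read it with [outlier_fraction()].
#' @export
remove_outliers <- function(data, z_threshold = 2.5, col = NULL) {
  if (z_threshold <= 0) stop("z_threshold must be > 0", call. = FALSE)
  s <- series_tbl(data, col)
  v <- s$data[[s$col]]
  ok <- !is.na(v)
  if (sum(ok) < 2L) {
    stop("need at least 2 non-missing values to estimate mean and SD",
      call. = FALSE
    )
  }
  m <- mean(v[ok])
  sd_ <- stats::sd(v[ok])
  flag <- if (is.na(sd_) || sd_ == 0) {
    rep(FALSE, length(v))
  } else {
    ok & abs(v - m) / sd_ > z_threshold
  }
  out <- s$data
  out[[s$col]][flag] <- NA
  out$outlier <- flag
  attr(out, "outlier_fraction") <- sum(flag) / sum(ok)
  out
}

#' @rdname remove_outliers
#' @export
outlier_fraction <- function(data) {
  f <- attr(data, "outlier_fraction")
  if (is.null(f) && "outlier" %in% names(data)) {
    f <- mean(data$outlier, na.rm = TRUE)
  }
  f
}

#' Absolute difference of a series
#'
#' Transforms a level series `{x_1 ... x_n}` into the magnitude-of-change
#' series `{|x_2 - x_1|, ..., |x_n - x_{n-1}|}` of length `n - 1`. This is
#' the primary dependent measure derived from the motion index: it makes a
#' video-derived activity level comparable with change-sensitive contact
#' sensors. A difference touching a missing value is missing.
#'
#' @param data A data frame with a value column, or a numeric vector.
#' @param col Name of the value column, or `NULL` to detect it.
#' @return A tibble of `n - 1` rows; any non-value columns (e.g. timestamps)
#'   keep the value of the later sample of each pair.
#' @export
absolute_difference <- function(data, col = NULL) {
  s <- series_tbl(data, col)
  v <- s$data[[s$col]]
  n <- length(v)
  if (n < 1L) stop("series must have length >= 1", call. = FALSE)
  out <- s$data[seq_len(max(n - 1L, 0L)) + if (n > 1L) 1L else 0L, , drop = FALSE]
  if (n > 1L) out[[s$col]] <- abs(v[-1L] - v[-n])
  out$outlier <- NULL
  out
}

#' Euclidean norm of a multi-axis series
#'
#' Collapses a tri-axis stream (accelerometer, 3-D position) to one magnitude
#' channel: per sample, `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param data A data frame with columns `x`, `y`, `z`, or a numeric matrix
#'   with 3 columns.
#' @return A tibble with a `value` column (and any timestamp column carried
#'   over).
#' @export
euclidean_norm <- function(data) {
  if (is.matrix(data)) {
    if (ncol(data) != 3L) {
      stop("matrix input must have exactly 3 columns (x, y, z)", call. = FALSE)
    }
    data <- tibble::tibble(x = data[, 1L], y = data[, 2L], z = data[, 3L])
  }
  if (!is.data.frame(data) || !all(c("x", "y", "z") %in% names(data))) {
    stop("data must contain columns x, y and z", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  keep <- setdiff(names(data), c("x", "y", "z"))
  out <- data[, keep, drop = FALSE]
  out$value <- sqrt(data$x^2 + data$y^2 + data$z^2)
  out
}

#' Reduce a pressure-grid series to mean pressure per frame
#'
#' For each frame of an `R x C` pressure-pad recording, sums the pressure on
#' every sensing element and divides by the number of elements, yielding one
#' mean-pressure sample per frame.
#'
#' @param frames An `R x C x n` array of nonnegative pressures, or a list of
#'   `R x C` matrices.
#' @return A tibble with columns `frame` and `value`.
#' @export
mean_grid <- function(frames) {
  fr <- if (is.list(frames)) frames else as_frame_list(frames)
  if (length(fr) == 0L || length(fr[[1L]]) == 0L) {
    stop("pressure-grid series must contain at least one nonempty frame",
      call. = FALSE
    )
  }
  tibble::tibble(
    frame = seq_along(fr),
    value = vapply(fr, function(m) mean(m), numeric(1))
  )
}

#' Equal-width window means
#'
#' Divides a series into `k` windows of equal width `floor(n / k)` samples
#' and returns the mean of each window (missing values ignored). The trailing
#' `n %% k` samples are dropped so that every window has exactly the same
#' width; a window whose samples are all missing is missing. Windowing is how
#' streams recorded at different rates (e.g. 30 fps video vs a 4 Hz pressure
#' pad) are brought onto a common time base for cross-correlation.
#'
#' @param data A data frame with a value column, or a numeric vector.
#' @param k Number of windows (default 10).
#' @param col Name of the value column, or `NULL` to detect it.
#' @return A tibble of class `"windowed_series"` with columns `window` and
#'   `mean`, and attribute `window_width`.
#' @export
window_means <- function(data, k = 10, col = NULL) {
  if (k < 2) stop("window count k must be >= 2", call. = FALSE)
  s <- series_tbl(data, col)
  v <- s$data[[s$col]]
  n <- length(v)
  if (n < k) {
    stop("series of length ", n, " is too short for k = ", k, " windows",
      call. = FALSE
    )
  }
  width <- n %/% k
  used <- v[seq_len(width * k)]
  means <- vapply(
    split(used, rep(seq_len(k), each = width)),
    function(w) if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE),
    numeric(1)
  )
  out <- tibble::tibble(window = seq_len(k), mean = unname(means))
  attr(out, "window_width") <- width
  class(out) <- c("windowed_series", class(out))
  out
}

#' Mean of a series, ignoring missing values
#'
#' @param data A data frame with a value column, or a numeric vector.
#' @param col Name of the value column, or `NULL` to detect it.
#' @return A single number.
#' @export
series_mean <- function(data, col = NULL) {
  s <- series_tbl(data, col)
  v <- s$data[[s$col]]
  if (all(is.na(v))) stop("all values are missing", call. = FALSE)
  mean(v, na.rm = TRUE)
}

#' Clean a raw series the standard way
#'
#' The canonical preprocessing order: burn-in discard, then one-pass z-score
#' outlier blanking, then (optionally) the absolute-difference transform.
#' Differencing is a per-stream switch: video-derived motion and position
#' series are differenced, whereas an accelerometer stream already measures
#' change and is not.
#'
#' @inheritParams discard_burn_in
#' @inheritParams remove_outliers
#' @param diff Apply [absolute_difference()] after cleaning? (default `TRUE`)
#' @return A cleaned tibble ready for [window_means()].
#' @export
prepare_series <- function(data, rate_hz = NULL, burn_in_seconds = 1,
                           burn_in_samples = NULL, auto = FALSE,
                           z_threshold = 2.5, diff = TRUE, col = NULL) {
  out <- discard_burn_in(
    data,
    rate_hz = rate_hz, burn_in_seconds = burn_in_seconds,
    burn_in_samples = burn_in_samples, auto = auto,
    z_threshold = z_threshold, col = col
  )
  out <- remove_outliers(out, z_threshold = z_threshold, col = col)
  frac <- attr(out, "outlier_fraction")
  if (diff) out <- absolute_difference(out, col = col)
  attr(out, "outlier_fraction") <- frac
  out
}

# ---- series I/O ----------------------------------------------------------

#' Read and write sensor series as delimited text
#'
#' Scalar series are stored as `timestamp_ms,value`; tri-axis series as
#' `timestamp_ms,x,y,z`. [read_series_csv()] detects which layout a file
#' uses. Pressure-grid recordings are stored by [write_pressure_grid()] as a
#' `key=value` header line declaring `rows`, `cols` and `rate_hz`, followed
#' by one flattened (row-major) CSV row per frame.
#'
#' @param data A tibble with `timestamp_ms` and either `value` or `x,y,z`.
#' @param path File path.
#' @return Readers return a tibble (or, for grids, a list with `frames`,
#'   `rate_hz`); writers return `path` invisibly.
#' @export
write_series_csv <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
    na = ""
  )
}

#' @rdname write_series_csv
#' @param frames An `R x C x n` array of pressures.
#' @param rate_hz Sampling rate recorded in the header.
#' @export
write_pressure_grid <- function(frames, path, rate_hz = 4) {
  fr <- if (is.list(frames)) frames else as_frame_list(frames)
  r <- nrow(fr[[1L]])
  c_ <- ncol(fr[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("rows=%d cols=%d rate_hz=%g", r, c_, rate_hz), con)
  for (m in fr) {
    writeLines(paste(as.vector(t(m)), collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_pressure_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("empty pressure-grid file: ", path, call. = FALSE)
  hdr <- strsplit(strsplit(lines[1L], "\\s+")[[1L]], "=")
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  r <- as.integer(vals[["rows"]])
  c_ <- as.integer(vals[["cols"]])
  body <- lines[-1L]
  frames <- array(0, dim = c(r, c_, length(body)))
  for (i in seq_along(body)) {
    v <- as.numeric(strsplit(body[i], ",")[[1L]])
    if (length(v) != r * c_) {
      stop("frame ", i, " has ", length(v), " values, expected ", r * c_,
        call. = FALSE
      )
    }
    frames[, , i] <- matrix(v, nrow = r, byrow = TRUE)
  }
  list(frames = frames, rate_hz = unname(vals["rate_hz"]))
}
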