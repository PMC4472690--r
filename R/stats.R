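# Validation statistics: between-subject Pearson correlations, normalized
# lagged cross-correlation of windowed series, best-positive-lag selection,
# one-sample t / Cohen's d summaries, and the subject-filtering rules.

#' Pearson correlation with missing-pair handling
#'
#' Sample product-moment correlation after dropping pairs with a missing
#' member. Used for the between-subject level of validation: per-subject
#' series means of one modality against another.
#'
#' @param x,y Numeric vectors of equal length.
#' @return The correlation, in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs, got ", length(x), call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: at least one input is constant", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Normalized lagged cross-correlation of two windowed series
#'
#' For two series `x`, `y` of equal length `n` and a nonnegative lag `k`,
#' computes
#' \deqn{C_{xy}(k) = \frac{\frac{1}{n}\sum_{t=1}^{n-k}(x_t - \bar x)(y_{t+k} - \bar y)}{s_x\, s_y}}
#' where the means and the (population, i.e. 1/n) standard deviations are
#' taken over the full series, so that `C(0) = 1` when `x = y`. Negative lags
#' use the antisymmetry `C_xy(-k) = C_yx(k)`. Values are correlations in
#' `[-1, 1]`; a positive lag `k` means `y` trails `x` by `k` windows.
#'
#' The best lag is selected by the best-positive-lag rule (see [best_lag()]):
#' among the evaluated lags, the one with the strongest positive correlation;
#' if none is positive, lag 0.
#'
#' @param x,y Numeric vectors of equal length, or `windowed_series` tibbles
#'   from [window_means()] (their `mean` column is used).
#' @param lags Integer lags to evaluate (default `-1:1`); every `|k|` must be
#'   `< n`.
#' @return An object of class `"cross_correlation"`: a list with `lags`,
#'   `values`, `best_lag`, `best_value`, `n`. Use [tidy()] / [glance()] for
#'   tibble views.
#' @examples
#' x <- c(0, 0, 1, 0)
#' y <- c(0, 0, 0, 1) # y trails x by one step
#' cross_correlation(x, y)$best_lag # 1
#' @export
cross_correlation <- function(x, y, lags = -1:1) {
  x <- windowed_values(x)
  y <- windowed_values(y)
  n <- length(x)
  if (length(y) != n) {
    stop("series must have equal length, got ", n, " and ", length(y),
      call. = FALSE
    )
  }
  if (n < 3L) stop("need series of length >= 3, got ", n, call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    stop("cross_correlation does not accept missing values; ",
      "window the series first (all-missing windows stay missing)",
      call. = FALSE
    )
  }
  lags <- as.integer(lags)
  if (any(abs(lags) >= n)) {
    stop("|lag| must be smaller than the series length ", n, call. = FALSE)
  }
  sx <- pop_sd(x)
  sy <- pop_sd(y)
  if (sx == 0 || sy == 0) {
    stop("cross-correlation undefined: at least one series is constant",
      call. = FALSE
    )
  }
  vals <- vapply(lags, function(k) ccov_pos_lag(x, y, k) / (sx * sy), numeric(1))
  best <- best_lag(vals, lags)
  structure(
    list(
      lags = lags, values = vals,
      best_lag = best$lag, best_value = best$value, n = n
    ),
    class = "cross_correlation"
  )
}

# Cross-covariance at lag k with full-series means; k < 0 via C_xy(-k) = C_yx(k).
ccov_pos_lag <- function(x, y, k) {
  if (k < 0L) {
    return(ccov_pos_lag(y, x, -k))
  }
  n <- length(x)
  t_ <- seq_len(n - k)
  sum((x[t_] - mean(x)) * (y[t_ + k] - mean(y))) / n
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

windowed_values <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("mean", "value", "motion_index"), names(x))[1L]
    if (is.na(col)) {
      stop("no 'mean' or 'value' column found in windowed input", call. = FALSE)
    }
    return(as.numeric(x[[col]]))
  }
  as.numeric(x)
}

#' Best positive lag
#'
#' Among correlations evaluated at a set of lags (by default -1, 0, +1),
#' selects the lag with the strongest *positive* correlation — the rule used
#' to tolerate slight temporal misalignment between recording streams. If no
#' correlation is positive, lag 0 is returned with its value; exact ties
#' prefer lag 0, then the smaller `|lag|`.
#'
#' @param values Correlation values, one per lag.
#' @param lags The corresponding integer lags (default `c(-1, 0, 1)`).
#' @return A list with elements `lag` and `value`.
#' @examples
#' best_lag(c(-.135, .855, .104)) # lag 0, value .855
#' @export
best_lag <- function(values, lags = c(-1, 0, 1)) {
  stopifnot(length(values) == length(lags))
  lags <- as.integer(lags)
  pos <- values > 0
  if (!any(pos)) {
    i0 <- match(0L, lags)
    if (is.na(i0)) i0 <- which.min(abs(lags))
    return(list(lag = lags[i0], value = values[i0]))
  }
  mx <- max(values[pos])
  cand <- which(pos & values == mx)
  # tie-break: lag 0 first, then smallest |lag|
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  list(lag = lags[cand[1L]], value = values[cand[1L]])
}

#' One-sample t and Cohen's d summary
#'
#' Summarises a set of per-subject correlations (or any per-subject scores)
#' against zero: `t = M / (SD / sqrt(n))` with `df = n - 1`, and the
#' one-sample effect size `d = M / SD`. Accepts either raw values or an
#' already-computed `(M, SD, n)` triple; both routes give identical results.
#'
#' @param x Raw values (missing values dropped), or `NULL` when supplying the
#'   triple.
#' @param mean,sd,n The precomputed mean, standard deviation (sample SD,
#'   must be > 0) and count (`n >= 2`).
#' @return A one-row tibble with columns `mean`, `sd`, `n`, `t`, `df`, `d`.
#' @examples
#' one_sample_summary(mean = .562, sd = .213, n = 27) # t(26) = 13.7
#' @export
one_sample_summary <- function(x = NULL, mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n)) {
    stop("supply either raw values x or all of mean, sd, n", call. = FALSE)
  }
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (is.na(sd) || sd <= 0) {
    stop("SD must be > 0 for a one-sample summary", call. = FALSE)
  }
  tibble::tibble(
    mean = mean, sd = sd, n = as.integer(n),
    t = mean / (sd / sqrt(n)),
    df = as.integer(n) - 1L,
    d = mean / sd
  )
}

#' Flag subjects whose group-level means are outlying
#'
#' Flags entries more than `z_threshold` (sample) standard deviations from
#' the group mean — the rule used to exclude a subject whose sensor record is
#' aberrant across all conditions. A constant group flags nothing.
#'
#' @param group_means Per-subject means (at least 3).
#' @param z_threshold SD-unit threshold (default 2).
#' @return A logical vector, `TRUE` for flagged entries.
#' @export
flag_outlying_series <- function(group_means, z_threshold = 2) {
  if (length(group_means) < 3L) {
    stop("need at least 3 values, got ", length(group_means), call. = FALSE)
  }
  m <- mean(group_means, na.rm = TRUE)
  sd_ <- stats::sd(group_means, na.rm = TRUE)
  if (is.na(sd_) || sd_ == 0) {
    return(rep(FALSE, length(group_means)))
  }
  !is.na(group_means) & abs(group_means - m) / sd_ > z_threshold
}

#' Exclude the lowest percentile of subject values
#'
#' Splits indices into kept / excluded sets by excluding the
#' `ceiling(n * p / 100)` smallest values; ties are broken by original order.
#' With 27 subjects and `p = 25` this excludes exactly 7 — the rule used to
#' drop subjects whose sensor channel recorded negligible movement.
#'
#' @param values Per-subject values (nonempty).
#' @param p Percentile in `[0, 100]` (default 25).
#' @return A list with integer index vectors `kept` and `excluded`.
#' @export
percentile_subset <- function(values, p = 25) {
  n <- length(values)
  if (n == 0L) stop("values must be nonempty", call. = FALSE)
  stopifnot(p >= 0, p <= 100)
  m <- ceiling(n * p / 100)
  ord <- order(values) # stable: ties keep original order
  excluded <- sort(ord[seq_len(m)])
  list(kept = setdiff(seq_len(n), excluded), excluded = excluded)
}

# ---- broom-style methods and printing ------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-correlation result
#'
#' @param x A `"cross_correlation"` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per lag (`lag`, `correlation`,
#'   `is_best`); `glance()`: a one-row tibble with `best_lag`, `best_value`,
#'   `lag0`, `n_windows`.
#' @export
tidy.cross_correlation <- function(x, ...) {
  tibble::tibble(
    lag = x$lags,
    correlation = x$values,
    is_best = x$lags == x$best_lag
  )
}

#' @rdname tidy.cross_correlation
#' @export
glance.cross_correlation <- function(x, ...) {
  i0 <- match(0L, x$lags)
  tibble::tibble(
    best_lag = x$best_lag,
    best_value = x$best_value,
    lag0 = if (is.na(i0)) NA_real_ else x$values[i0],
    n_windows = x$n
  )
}

#' @export
print.cross_correlation <- function(x, ...) {
  cat("<normalized cross-correlation> n =", x$n, "windows\n")
  cat(
    paste0(
      "  lag ", format(x$lags), ": ", format(round(x$values, 3), nsmall = 3),
      ifelse(x$lags == x$best_lag, "  <- best", ""),
      collapse = "\n"
    ),
    "\n"
  )
  invisible(x)
}
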