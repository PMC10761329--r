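#' Parameters for the absolute activity index
#'
#' The activity index is the square root of the mean, over the three axes,
#' of the windowed signal variance of raw acceleration, optionally corrected
#' for a systematic device-noise variance `sigma_i^2`:
#' `AI = sqrt(max(0, mean_m(var_m) - sigma_i^2))`. With the device used
#' here the systematic noise is negligible, so `sigma_i = 0` by default and
#' the correction (and the `max(0, .)` guard) is inert.
#'
#' @param window_seconds variance window length H in seconds (default 1;
#'   at 32 Hz this is 32 samples per window).
#' @param sigma_i systematic noise SD in g subtracted inside the formula
#'   (default 0).
#' @param variance_estimator `"sample_n_minus_1"` (unbiased, default) or
#'   `"population_n"`.
#' @param min_valid_fraction_per_window fraction of a window's samples that
#'   must be valid and on-body for the window to yield a value (default 1:
#'   all samples required).
#' @param min_valid_seconds_per_minute minimum number of valid per-second
#'   values required for a per-minute average (default 30).
#' @return an object of class `ai_params`.
#' @export
ai_params <- function(window_seconds = 1, sigma_i = 0,
                      variance_estimator = c("sample_n_minus_1", "population_n"),
                      min_valid_fraction_per_window = 1.0,
                      min_valid_seconds_per_minute = 30L) {
  variance_estimator <- match.arg(variance_estimator)
  stopifnot(window_seconds > 0, sigma_i >= 0,
            min_valid_fraction_per_window > 0,
            min_valid_fraction_per_window <= 1,
            min_valid_seconds_per_minute >= 1)
  structure(list(window_seconds = window_seconds, sigma_i = sigma_i,
                 variance_estimator = variance_estimator,
                 min_valid_fraction_per_window = min_valid_fraction_per_window,
                 min_valid_seconds_per_minute = as.integer(min_valid_seconds_per_minute)),
            class = "ai_params")
}

axis_variance <- function(x, estimator) {
  x <- x[!is.na(x)]
  k <- length(x)
  if (k < 2L) return(NA_real_)
  mu <- mean(x)
  ss <- sum((x - mu)^2)
  if (estimator == "sample_n_minus_1") ss / (k - 1) else ss / k
}

#' Activity index of a single window
#'
#' Reference (scalar) implementation for one variance window: typically a
#' 32 x 3 matrix covering one second at 32 Hz. `NA` rows count as invalid
#' samples; the window returns `NA` when fewer than
#' `min_valid_fraction_per_window` of its samples are usable.
#'
#' @param window numeric matrix, one row per sample, columns x/y/z, in g.
#' @param params an [ai_params()].
#' @param sample_rate_hz grid rate, used to check the window covers exactly
#'   `window_seconds` (default 32).
#' @return a single non-negative AI value in g, or `NA` for an invalid
#'   window.
#' @export
ai_second <- function(window, params = ai_params(), sample_rate_hz = 32) {
  window <- as.matrix(window)
  expected <- round(params$window_seconds * sample_rate_hz)
  if (nrow(window) != expected)
    stop(sprintf("window has %d samples; expected H * rate = %d",
                 nrow(window), expected))
  ok <- stats::complete.cases(window)
  if (sum(ok) < params$min_valid_fraction_per_window * expected ||
      sum(ok) < 2L)
    return(NA_real_)
  v <- vapply(1:3, function(j)
    axis_variance(window[ok, j], params$variance_estimator), numeric(1))
  sqrt(max(0, mean(v) - params$sigma_i^2))
}

#' Per-minute aggregation of per-second activity-index values
#'
#' @param per_second numeric vector of up to 60 per-second AI values
#'   (`NA` = invalid second).
#' @param params an [ai_params()].
#' @return the mean of the valid values when at least
#'   `min_valid_seconds_per_minute` are valid, else `NA`.
#' @export
ai_minute <- function(per_second, params = ai_params()) {
  if (length(per_second) > 60L) stop("a minute holds at most 60 seconds")
  ok <- !is.na(per_second)
  if (sum(ok) < params$min_valid_seconds_per_minute) return(NA_real_)
  mean(per_second[ok])
}

#' Compute the activity-index series of a recording
#'
#' Tiles the recording into non-overlapping, clock-aligned windows of
#' `window_seconds` (1 s by default), computes the AI of each window from
#' samples that are both valid and on-body, and averages the per-second
#' values within each minute. Off-body exclusion must happen before this
#' step: run [detect_offbody()] (or set `on_body_mask`) first.
#'
#' The vectorized computation is exactly the per-window formula of
#' [ai_second()]; equivalence is enforced by tests against the scalar loop.
#'
#' @param rec an [acc_recording()] whose start time falls on a whole minute.
#' @param params an [ai_params()].
#' @return an object of class `ai_series`: list with `per_second` and
#'   `per_minute` data.frames (`time`, `ai`, `valid`; per-minute rows also
#'   carry `n_valid_seconds`) and the `params` used.
#' @export
compute_ai <- function(rec, params = ai_params()) {
  r <- rec$sample_rate_hz
  w <- round(params$window_seconds * r)
  n <- nrow(rec$samples)
  n_win <- n %/% w
  if (n_win == 0L) stop("recording shorter than one AI window")
  nw <- n_win * w
  use <- rec$valid_mask[seq_len(nw)] & rec$on_body_mask[seq_len(nw)]
  all_ok <- all(use)
  bad <- !use
  k <- if (all_ok) rep(w, n_win) else .colSums(use, w, n_win)
  sum_v <- matrix(0, n_win, 3)
  for (j in 1:3) {
    x0 <- rec$samples[seq_len(nw), j]
    if (!all_ok) x0[bad] <- 0
    mu <- .colSums(x0, w, n_win) / k
    # centre before squaring: with a ~1 g gravity offset the one-pass
    # sum-of-squares form loses the low-variance windows to cancellation
    xc <- x0 - rep(mu, each = w)
    if (!all_ok) xc[bad] <- 0
    ss <- .colSums(xc * xc, w, n_win)
    denom <- if (params$variance_estimator == "sample_n_minus_1") k - 1 else k
    v <- ss / denom
    v[k < 2L] <- NA_real_
    sum_v[, j] <- v
  }
  ai_sec <- sqrt(pmax(0, rowMeans(sum_v) - params$sigma_i^2))
  too_few <- k < params$min_valid_fraction_per_window * w
  ai_sec[too_few] <- NA_real_
  # numerical guard: windowed two-pass cancellation can leave tiny negatives
  ai_sec[is.nan(ai_sec)] <- NA_real_

  sec_per_min <- round(60 / params$window_seconds)
  n_min <- n_win %/% sec_per_min
  per_minute_ai <- rep(NA_real_, n_min)
  n_valid_sec <- integer(n_min)
  if (n_min > 0L) {
    a <- matrix(ai_sec[seq_len(n_min * sec_per_min)], nrow = sec_per_min)
    okm <- !is.na(a)
    n_valid_sec <- .colSums(okm, sec_per_min, n_min)
    a0 <- a; a0[!okm] <- 0
    per_minute_ai <- .colSums(a0, sec_per_min, n_min) / n_valid_sec
    per_minute_ai[n_valid_sec < params$min_valid_seconds_per_minute] <- NA_real_
  }
  structure(list(
    per_second = data.frame(
      time = rec$start_time + (seq_len(n_win) - 1) * params$window_seconds,
      ai = ai_sec, valid = !is.na(ai_sec)),
    per_minute = data.frame(
      time = rec$start_time + (seq_len(n_min) - 1) * 60,
      ai = per_minute_ai, valid = !is.na(per_minute_ai),
      n_valid_seconds = n_valid_sec),
    params = params, start_time = rec$start_time),
    class = "ai_series")
}

#' @export
print.ai_series <- function(x, ...) {
  cat(sprintf("<ai_series> %d seconds, %d minutes (%.1f%% valid minutes)\n",
              nrow(x$per_second), nrow(x$per_minute),
              100 * mean(x$per_minute$valid)))
  invisible(x)
}

# valid per-minute AI values whose epochs fall in [start, end)
minute_values <- function(ai, start, end) {
  m0 <- round(secs_between(ai$start_time, start) / 60) + 1
  m1 <- round(secs_between(ai$start_time, end) / 60)
  m0 <- max(m0, 1L); m1 <- min(m1, nrow(ai$per_minute))
  if (m1 < m0) return(numeric(0))
  v <- ai$per_minute$ai[m0:m1]
  v[!is.na(v)]
}
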