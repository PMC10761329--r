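# Independent oracle implementations used to check the package's vectorized
# code paths. Kept deliberately naive: plain loops, base-R primitives.

BRU <- "Europe/Brussels"

bru_time <- function(s) as.POSIXct(s, tz = BRU)

# per-second AI by looping scalar windows (ai_second is itself a scalar
# two-pass implementation; this drives it window by window)
naive_ai_per_second <- function(rec, params = ai_params()) {
  r <- rec$sample_rate_hz
  w <- round(params$window_seconds * r)
  n_win <- nrow(rec$samples) %/% w
  out <- rep(NA_real_, n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1) * w + 1):(i * w)
    win <- rec$samples[idx, , drop = FALSE]
    bad <- !(rec$valid_mask[idx] & rec$on_body_mask[idx])
    win[bad, ] <- NA_real_
    out[i] <- ai_second(win, params, r)
  }
  out
}

# exhaustive two-tailed signed-rank p over all sign assignments
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  total <- 2^n
  Ws <- numeric(total)
  for (code in 0:(total - 1)) {
    bits <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    Ws[code + 1] <- sum(rk[bits])
  }
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# independent eligibility filter: direct loops, %u day-of-week codes,
# per-sample ratio arithmetic written from scratch
brute_ratio <- function(rec, s, e) {
  r <- rec$sample_rate_hz
  t0 <- as.numeric(rec$start_time)
  i0 <- as.integer(round((as.numeric(s) - t0) * r)) + 1L
  i1 <- as.integer(round((as.numeric(e) - t0) * r))
  mean(rec$valid_mask[i0:i1] & rec$on_body_mask[i0:i1])
}

brute_overlaps_night <- function(s, e, tz) {
  d <- as.Date(format(s - 86400, "%Y-%m-%d"))
  for (k in 0:(as.integer(as.Date(format(e, "%Y-%m-%d")) - d))) {
    ns <- as.POSIXct(paste(d + k, "23:00:00"), tz = tz)
    ne <- as.POSIXct(paste(d + k + 1, "07:30:00"), tz = tz)
    if (as.numeric(s) < as.numeric(ne) && as.numeric(ns) < as.numeric(e))
      return(TRUE)
  }
  FALSE
}

brute_candidates <- function(attack, log, rec, holidays = as.Date(character()),
                             min_ratio = 0.75) {
  tz <- attr(rec$start_time, "tzone")
  onset <- attack$onset; aend <- attack$end
  clock <- format(onset, "%H:%M:%S")
  dur <- as.numeric(aend) - as.numeric(onset)
  weekend <- format(onset, "%u") %in% c("6", "7")
  d0 <- as.Date(format(log$study_start, "%Y-%m-%d"))
  ndays <- ceiling((as.numeric(log$study_end) - as.numeric(log$study_start)) /
                     86400)
  bounds <- unlist(lapply(log$events, function(a)
    c(as.numeric(a$onset), as.numeric(a$end))))
  found <- c()
  for (off in 0:ndays) {
    d <- d0 + off
    if (d == as.Date(format(onset, "%Y-%m-%d"))) next
    cs <- as.POSIXct(paste(d, clock), tz = tz)
    ce <- cs + dur
    if ((format(cs, "%u") %in% c("6", "7")) != weekend) next
    if (as.Date(format(cs, "%Y-%m-%d")) %in% holidays ||
        as.Date(format(ce - 1, "%Y-%m-%d")) %in% holidays) next
    if (as.numeric(cs) < as.numeric(rec$start_time)) next
    if (as.numeric(ce) > as.numeric(rec$start_time) +
        nrow(rec$samples) / rec$sample_rate_hz) next
    ok <- TRUE
    for (b in bounds) {
      dist <- if (b >= as.numeric(cs) && b < as.numeric(ce)) 0 else
        min(abs(b - as.numeric(cs)), abs(b - as.numeric(ce)))
      if (dist < 86400) { ok <- FALSE; break }
    }
    if (!ok) next
    if (brute_ratio(rec, cs, ce) < min_ratio) next
    found <- c(found, as.numeric(cs))
  }
  found
}

brute_eligibility_status <- function(log, rec,
                                     holidays = as.Date(character()),
                                     min_ratio = 0.75) {
  tz <- attr(rec$start_time, "tzone")
  vapply(log$events, function(a) {
    if (brute_overlaps_night(a$onset, a$end, tz)) return("nighttime")
    if (brute_ratio(rec, a$onset, a$end) < min_ratio)
      return("low_data_ratio")
    if (!length(brute_candidates(a, log, rec, holidays, min_ratio)))
      return("no_match")
    "eligible"
  }, character(1))
}

# valid per-minute AI values in [start, end), selected by timestamp
minute_values_for_test <- function(ai, start, end) {
  sel <- ai$per_minute$time >= start & ai$per_minute$time < end
  v <- ai$per_minute$ai[sel]
  v[!is.na(v)]
}

# small random recording on the grid (gravity offset + mixed-scale noise)
random_recording <- function(n_sec, rate = 32, seed = 1,
                             start = bru_time("2024-04-08 00:00:00"),
                             gap_frac = 0) {
  set.seed(seed)
  n <- n_sec * rate
  sds <- sample(c(0.005, 0.03, 0.1, 0.3), n_sec, replace = TRUE)
  g <- matrix(rnorm(3), n, 3, byrow = TRUE)
  g <- g / sqrt(sum(g[1, ]^2))
  m <- g + matrix(rnorm(3 * n), n, 3) * rep(sds, each = rate)
  m <- pmin(pmax(m, -2), 2)
  valid <- rep(TRUE, n)
  if (gap_frac > 0) valid[sample(n, round(gap_frac * n))] <- FALSE
  acc_recording(m, start, rate, valid_mask = valid)
}
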