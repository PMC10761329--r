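#' Calendar configuration for eligibility rules
#'
#' Wall-clock conventions used by the eligibility filters: the nighttime
#' window (crossing midnight), the weekend day set defining the
#' weekday/weekend day-type, and holiday dates excluded as comparison days.
#' All rules operate on local wall-clock time in the recording's zone.
#'
#' @param nighttime_start,nighttime_end wall-clock times `"HH:MM"`
#'   (defaults 23:00 and 07:30; the window crosses midnight).
#' @param holiday_dates `Date` vector of excluded calendar dates (see
#'   [belgian_holidays()]).
#' @param weekend_days day names counted as weekend.
#' @return an object of class `calendar_config`.
#' @export
calendar_config <- function(nighttime_start = "23:00", nighttime_end = "07:30",
                            holiday_dates = as.Date(character()),
                            weekend_days = c("Saturday", "Sunday")) {
  parse_clock <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60
  }
  structure(list(night_start_s = parse_clock(nighttime_start),
                 night_end_s = parse_clock(nighttime_end),
                 nighttime_start = nighttime_start,
                 nighttime_end = nighttime_end,
                 holiday_dates = as.Date(holiday_dates),
                 weekend_days = weekend_days),
            class = "calendar_config")
}

#' Fraction of usable data in an interval
#'
#' Fraction of the grid samples in `[start, end)` that are both present
#' (valid) and on-body. Eligibility requires at least 0.75 (boundary
#' inclusive: exactly 25% missing still passes).
#'
#' @param rec an [acc_recording()].
#' @param start,end `POSIXct` interval bounds; must lie within the
#'   recording span.
#' @return a fraction in `[0, 1]`.
#' @export
data_ratio <- function(rec, start, end) {
  idx <- sample_index_range(rec, start, end)
  if (idx["first"] < 1L || idx["last"] > nrow(rec$samples))
    stop("interval ", format(start), " .. ", format(end),
         " lies outside the recording span")
  if (idx["last"] < idx["first"]) stop("empty interval")
  i <- idx["first"]:idx["last"]
  mean(rec$valid_mask[i] & rec$on_body_mask[i])
}

# does [start, end) intersect any nightly window?
overlaps_nighttime <- function(start, end, cal) {
  d0 <- local_date(start) - 1
  d1 <- local_date(end)
  tz <- attr(start, "tzone")
  for (d in seq(d0, d1, by = "day")) {
    d <- as.Date(d, origin = "1970-01-01")
    ns <- at_clock(d, cal$night_start_s, tz)
    ne <- at_clock(d + 1, cal$night_end_s, tz)
    if (secs_between(start, ne) > 0 && secs_between(ns, end) > 0)
      return(TRUE)
  }
  FALSE
}

#' Daytime classification of an attack
#'
#' An attack is daytime-eligible when its `[onset, end)` interval has an
#' empty intersection with every nightly window (23:00-07:30 by default).
#'
#' @param attack an [attack_event()] (or anything with `onset`/`end`).
#' @param cal a [calendar_config()].
#' @return `TRUE`/`FALSE`.
#' @export
is_daytime <- function(attack, cal = calendar_config()) {
  !overlaps_nighttime(attack$onset, attack$end, cal)
}

# minimum time (seconds) between any point of [s, e) and the boundary b
# (numeric epoch-second arguments)
boundary_distance <- function(s, e, b) {
  if (b >= s && b < e) return(0)
  min(abs(s - b), abs(e - b))
}

# >= 24 h from the start AND end of every attack (numeric boundary vector)
clear_of_attacks <- function(s, e, boundaries, min_secs = 86400) {
  inside <- boundaries >= s & boundaries < e
  if (any(inside)) return(FALSE)
  all(pmin(abs(s - boundaries), abs(e - boundaries)) >= min_secs)
}

attack_boundaries <- function(log) {
  if (!length(log$events)) return(numeric(0))
  c(vapply(log$events, function(a) as.numeric(a$onset), numeric(1)),
    vapply(log$events, function(a) as.numeric(a$end), numeric(1)))
}

day_type <- function(t, cal) {
  if (weekdays(t, abbreviate = FALSE) %in% cal$weekend_days) "weekend"
  else "weekday"
}

#' Matched non-attack comparison intervals for an attack
#'
#' Candidates are the same wall-clock `[onset, end)` range on every other
#' day of the study period with the same day-type (weekday vs weekend) as
#' the attack's onset date. A candidate is kept iff it is at least 24 h
#' distant from the start and end of every attack in the log (boundary
#' inclusive), its date is not a configured holiday, it lies inside the
#' recording span, and its data ratio is at least `min_ratio`.
#'
#' @param attack an [attack_event()].
#' @param log the full [event_log()] (all attacks enforce the 24-h rule).
#' @param rec an [acc_recording()] with `on_body_mask` populated.
#' @param cal a [calendar_config()].
#' @param min_ratio minimum data ratio (default 0.75).
#' @param clock_start_s,clock_end_s optional wall-clock range override in
#'   seconds since midnight (used for onset-relative bins); defaults to the
#'   attack's own clock range.
#' @return data.frame of candidates (`start`, `end`, `data_ratio`), sorted
#'   by date; zero rows when no candidate qualifies.
#' @export
find_non_ch_intervals <- function(attack, log, rec, cal = calendar_config(),
                                  min_ratio = 0.75,
                                  clock_start_s = NULL, clock_end_s = NULL) {
  tz <- attr(rec$start_time, "tzone")
  onset_date <- local_date(attack$onset)
  if (is.null(clock_start_s)) clock_start_s <- clock_secs(attack$onset)
  if (is.null(clock_end_s)) {
    span <- secs_between(attack$onset, attack$end)
    clock_end_s <- clock_start_s + span
  }
  anchor_date <- onset_date + clock_start_s %/% 86400
  type <- day_type(attack$onset, cal)
  d0 <- local_date(log$study_start)
  d1 <- local_date(log$study_end)
  bounds <- attack_boundaries(log)
  rec0 <- as.numeric(rec$start_time)
  rec1 <- as.numeric(rec_end_time(rec))
  out <- list()
  for (d in seq(d0, d1, by = "day")) {
    d <- as.Date(d, origin = "1970-01-01")
    if (d == anchor_date) next
    # day-type and holiday checks on the candidate's own start date,
    # before any POSIXct construction
    cd <- d + clock_start_s %/% 86400
    if ((format(cd, "%A") %in% cal$weekend_days) != (type == "weekend")) next
    ed <- d + (clock_end_s - 1) %/% 86400
    if (cd %in% cal$holiday_dates || ed %in% cal$holiday_dates) next
    cs <- at_clock(d, clock_start_s, tz)
    ce <- at_clock(d, clock_end_s, tz)      # crosses midnight transparently
    csn <- as.numeric(cs); cen <- as.numeric(ce)
    if (csn < rec0 || cen > rec1) next
    if (!clear_of_attacks(csn, cen, bounds)) next
    ratio <- data_ratio(rec, cs, ce)
    if (ratio < min_ratio) next
    out[[length(out) + 1L]] <- data.frame(start = cs, end = ce,
                                          data_ratio = ratio)
  }
  if (!length(out))
    return(data.frame(start = as.POSIXct(character(), tz = tz),
                      end = as.POSIXct(character(), tz = tz),
                      data_ratio = numeric()))
  do.call(rbind, out)
}

#' Pool per-minute AI values over matched non-attack intervals
#'
#' Concatenates the valid per-minute AI values of every candidate interval
#' into the single comparison distribution paired against the attack.
#' Order of candidates is irrelevant for every downstream quantile feature.
#'
#' @param candidates data.frame from [find_non_ch_intervals()].
#' @param ai an `ai_series` from [compute_ai()].
#' @return numeric vector of pooled per-minute AI values; errors when the
#'   candidate list is empty (the attack is not eligible).
#' @export
pool_non_ch <- function(candidates, ai) {
  if (!nrow(candidates))
    stop("no eligible non-attack intervals: attack is not analyzable")
  unlist(lapply(seq_len(nrow(candidates)), function(i)
    minute_values(ai, candidates$start[i], candidates$end[i])),
    use.names = FALSE)
}

#' Onset-relative analysis bins
#'
#' The seven fixed windows anchored at attack onset: 3-1 h before, 1 h to
#' 30 min before, 30 min to onset, onset to 30 min after, 30 min to 1 h
#' after, 1-2 h after, and 2-3 h after.
#'
#' @param attack an [attack_event()] (only `onset` is used).
#' @return data.frame with `bin_id`, `start`, `end`.
#' @export
onset_relative_bins <- function(attack) {
  offs <- rbind(c(-180, -60), c(-60, -30), c(-30, 0), c(0, 30),
                c(30, 60), c(60, 120), c(120, 180))
  ids <- c("-3h..-1h", "-1h..-30m", "-30m..0", "0..+30m",
           "+30m..+1h", "+1h..+2h", "+2h..+3h")
  data.frame(bin_id = ids,
             start = attack$onset + offs[, 1] * 60,
             end = attack$onset + offs[, 2] * 60)
}

#' Per-attack eligibility funnel
#'
#' Applies the attack-side eligibility rules in order — daytime (no overlap
#' with the nighttime window), data ratio >= `min_ratio` over the attack
#' interval, and existence of at least one matched non-attack interval —
#' and records the first failing rule for each attack. This reproduces the
#' total / daytime / >=75% data / eligible-match funnel used to report
#' attack attrition.
#'
#' @param log an [event_log()].
#' @param rec an [acc_recording()] with `on_body_mask` populated.
#' @param cal a [calendar_config()].
#' @param min_ratio minimum data ratio (default 0.75).
#' @return an object of class `eligibility`: list with `ledger` (one row
#'   per attack: `attack_id`, `onset`, `end`, `status` in
#'   nighttime/low_data_ratio/no_match/eligible, `data_ratio`,
#'   `n_candidates`) and `candidates` (list of candidate data.frames for
#'   eligible attacks).
#' @export
attack_eligibility <- function(log, rec, cal = calendar_config(),
                               min_ratio = 0.75) {
  n <- length(log$events)
  status <- character(n); ratio <- rep(NA_real_, n); ncand <- integer(n)
  candidates <- vector("list", n)
  for (i in seq_len(n)) {
    a <- log$events[[i]]
    if (!is_daytime(a, cal)) { status[i] <- "nighttime"; next }
    r <- data_ratio(rec, a$onset, a$end)
    ratio[i] <- r
    if (r < min_ratio) { status[i] <- "low_data_ratio"; next }
    cand <- find_non_ch_intervals(a, log, rec, cal, min_ratio)
    ncand[i] <- nrow(cand)
    if (!nrow(cand)) { status[i] <- "no_match"; next }
    status[i] <- "eligible"
    candidates[[i]] <- cand
  }
  ledger <- data.frame(
    attack_id = seq_len(n),
    onset = if (n) do.call(c, lapply(log$events, `[[`, "onset")) else
      as.POSIXct(character()),
    end = if (n) do.call(c, lapply(log$events, `[[`, "end")) else
      as.POSIXct(character()),
    status = status, data_ratio = ratio, n_candidates = ncand)
  structure(list(ledger = ledger, candidates = candidates,
                 min_ratio = min_ratio),
            class = "eligibility")
}

#' @export
print.eligibility <- function(x, ...) {
  tab <- table(factor(x$ledger$status,
                      levels = c("eligible", "nighttime", "low_data_ratio",
                                 "no_match")))
  cat(sprintf("<eligibility> %d attacks: %s\n", nrow(x$ledger),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
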