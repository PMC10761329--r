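#' Tri-axial acceleration recording on a uniform sample grid
#'
#' Container for a wrist-accelerometer stream. Samples live on a uniform
#' grid anchored at `start_time`: sample `i` (1-based) is taken at
#' `start_time + (i - 1) / sample_rate_hz` seconds. Streaming gaps are
#' represented by `valid_mask = FALSE` at their grid positions, never by
#' deleting rows, so windowed statistics and data ratios stay trivial.
#' `on_body_mask` starts all-`TRUE` and is populated by [detect_offbody()].
#'
#' @param samples numeric matrix with 3 columns (x, y, z), in g.
#' @param start_time `POSIXct` (timezone-aware) time of the first sample;
#'   must fall on a whole second.
#' @param sample_rate_hz integer samples per second.
#' @param valid_mask logical vector, `FALSE` where the sample is missing.
#' @param on_body_mask logical vector, `FALSE` where the device was off-body.
#' @param range_g full-scale range of the accelerometer in g (default 2).
#' @return an object of class `acc_recording`.
#' @export
acc_recording <- function(samples, start_time, sample_rate_hz,
                          valid_mask = NULL, on_body_mask = NULL,
                          range_g = 2) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns (x, y, z)")
  storage.mode(samples) <- "double"
  colnames(samples) <- c("x", "y", "z")
  n <- nrow(samples)
  assert_posixct(start_time, "start_time")
  if (abs(as.numeric(start_time) %% 1) > 1e-9)
    stop("start_time must fall on a whole second")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0L)
    stop("sample_rate_hz must be a positive integer")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  if (is.null(on_body_mask)) on_body_mask <- rep(TRUE, n)
  if (length(valid_mask) != n || length(on_body_mask) != n)
    stop("masks must have one entry per sample")
  if (n) {
    rng <- range(samples)
    if (anyNA(rng))
      rng <- range(samples[valid_mask, , drop = FALSE], na.rm = TRUE)
    if (any(is.finite(rng)) && max(abs(rng)) > range_g + 1e-9)
      stop(sprintf("valid samples exceed the ±%g g range", range_g))
  }
  structure(
    list(samples = samples, start_time = start_time,
         sample_rate_hz = sample_rate_hz,
         valid_mask = as.logical(valid_mask),
         on_body_mask = as.logical(on_body_mask),
         range_g = range_g),
    class = "acc_recording")
}

#' @export
print.acc_recording <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- n / x$sample_rate_hz
  cat(sprintf("<acc_recording> %d samples @ %d Hz (%.2f h), start %s [%s]\n",
              n, x$sample_rate_hz, dur / 3600,
              format(x$start_time, "%Y-%m-%d %H:%M:%S"),
              format(x$start_time, "%Z")))
  cat(sprintf("  valid: %.1f%%  on-body: %.1f%%\n",
              100 * mean(x$valid_mask), 100 * mean(x$on_body_mask)))
  invisible(x)
}

#' @export
length.acc_recording <- function(x) nrow(x$samples)

rec_end_time <- function(rec) {
  rec$start_time + nrow(rec$samples) / rec$sample_rate_hz
}

# grid index range (1-based, half-open interval [start, end)), rounded to
# the nearest grid point to absorb POSIXct floating-point noise
sample_index_range <- function(rec, start, end) {
  r <- rec$sample_rate_hz
  i0 <- round(secs_between(rec$start_time, start) * r) + 1
  i1 <- round(secs_between(rec$start_time, end) * r)
  c(first = i0, last = i1)
}

#' Single attack event
#'
#' @param onset,end `POSIXct` onset and end (minute precision expected);
#'   `end` must be after `onset`.
#' @param intensity integer pain score 1-5 (5-point Likert).
#' @param treatments character vector of acute-treatment labels, from
#'   `TREATMENT_LABELS` (oxygen, sumatriptan_sc, zolmitriptan_nasal,
#'   combination_analgesic, unspecified, none).
#' @param effective logical or `NA` (unknown) treatment-effectiveness flag.
#' @return an object of class `attack_event`.
#' @export
attack_event <- function(onset, end, intensity,
                         treatments = "none", effective = NA) {
  assert_posixct(onset, "onset"); assert_posixct(end, "end")
  if (!secs_between(onset, end) > 0) stop("end must be after onset")
  intensity <- as.integer(intensity)
  if (is.na(intensity) || !intensity %in% 1:5)
    stop("intensity must be an integer in 1..5")
  treatments <- as.character(treatments)
  bad <- setdiff(treatments, TREATMENT_LABELS)
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  structure(list(onset = onset, end = end, intensity = intensity,
                 treatments = treatments, effective = effective),
            class = "attack_event")
}

#' Recognised acute-treatment labels
#' @export
TREATMENT_LABELS <- c("oxygen", "sumatriptan_sc", "zolmitriptan_nasal",
                      "combination_analgesic", "unspecified", "none")

#' Ordered log of attack events over a study period
#'
#' Events are sorted by onset. Overlapping events are accepted with a
#' warning (registration data can legitimately contain them).
#'
#' @param events list of [attack_event()] objects.
#' @param study_start,study_end `POSIXct` study boundaries; all events must
#'   fall inside them.
#' @return an object of class `event_log`.
#' @export
event_log <- function(events, study_start, study_end) {
  assert_posixct(study_start, "study_start")
  assert_posixct(study_end, "study_end")
  stopifnot(all(vapply(events, inherits, logical(1), "attack_event")))
  if (length(events)) {
    ord <- order(vapply(events, function(e) as.numeric(e$onset), numeric(1)))
    events <- events[ord]
    for (e in events)
      if (secs_between(study_start, e$onset) < 0 ||
          secs_between(e$end, study_end) < 0)
        stop("event outside the study period: ",
             format(e$onset), " .. ", format(e$end))
    if (length(events) > 1L) {
      on <- vapply(events, function(e) as.numeric(e$onset), numeric(1))
      en <- vapply(events, function(e) as.numeric(e$end), numeric(1))
      if (any(on[-1] < en[-length(en)]))
        warning("event log contains overlapping attacks")
    }
  }
  structure(list(events = events, study_start = study_start,
                 study_end = study_end),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d attacks, study %s .. %s\n", length(x$events),
              format(x$study_start, "%Y-%m-%d"), format(x$study_end, "%Y-%m-%d")))
  invisible(x)
}

#' @export
length.event_log <- function(x) length(x$events)

#' Event log as a data.frame
#'
#' @param x an `event_log`.
#' @param ... unused.
#' @return a data.frame with one row per attack (onset, end, intensity,
#'   treatments collapsed with `;`, effective).
#' @export
as.data.frame.event_log <- function(x, ...) {
  if (!length(x$events))
    return(data.frame(onset = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      intensity = integer(), treatments = character(),
                      effective = logical()))
  data.frame(
    onset = do.call(c, lapply(x$events, `[[`, "onset")),
    end = do.call(c, lapply(x$events, `[[`, "end")),
    intensity = vapply(x$events, `[[`, integer(1), "intensity"),
    treatments = vapply(x$events, function(e)
      paste(e$treatments, collapse = ";"), character(1)),
    effective = vapply(x$events, function(e)
      as.logical(e$effective)[1], logical(1)))
}
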