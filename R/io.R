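#' Read an Empatica-E4-dialect ACC CSV
#'
#' The E4 export dialect for the accelerometer channel: line 1 holds the
#' UNIX epoch start timestamp (repeated across the three columns), line 2
#' the sample rate in Hz, and every following line one sample as integer
#' counts where 64 counts = 1 g. Non-numeric body rows are kept on the grid
#' but masked invalid (with a warning), so the implied uniform grid is
#' never broken.
#'
#' @param path path to the CSV file.
#' @param tz timezone used to interpret the epoch timestamp (the epoch is
#'   absolute; `tz` only sets the wall clock used downstream).
#' @param range_g full-scale range in g.
#' @return an [acc_recording()].
#' @export
read_e4_acc_csv <- function(path, tz = "UTC", range_g = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("malformed E4 file (need header timestamp + sample-rate lines): ", path)
  parse_row <- function(line) suppressWarnings(
    as.numeric(strsplit(line, ",", fixed = TRUE)[[1]]))
  hdr <- parse_row(lines[1])
  rate <- parse_row(lines[2])
  if (!length(hdr) || anyNA(hdr) || length(unique(hdr)) != 1L)
    stop("malformed E4 header at line 1: ", lines[1])
  if (!length(rate) || anyNA(rate) || length(unique(rate)) != 1L || rate[1] <= 0)
    stop("malformed E4 sample-rate at line 2: ", lines[2])
  start <- as.POSIXct(hdr[1], origin = "1970-01-01", tz = tz)
  body <- lines[-(1:2)]
  n <- length(body)
  if (n == 0L)
    return(acc_recording(matrix(numeric(0), 0, 3), start, rate[1],
                         range_g = range_g))
  dt <- data.table::fread(text = body, header = FALSE, sep = ",",
                          colClasses = "character", fill = TRUE)
  if (ncol(dt) < 3L) dt[, (paste0("V", (ncol(dt) + 1):3)) := NA_character_]
  m <- suppressWarnings(
    cbind(as.numeric(dt[[1]]), as.numeric(dt[[2]]), as.numeric(dt[[3]])))
  valid <- stats::complete.cases(m)
  if (!all(valid)) {
    # literal NA rows are the dialect's gap representation; anything else
    # unparseable is worth a warning
    na_lit <- (is.na(dt[[1]]) | dt[[1]] %in% c("NA", "")) &
      (is.na(dt[[2]]) | dt[[2]] %in% c("NA", "")) &
      (is.na(dt[[3]]) | dt[[3]] %in% c("NA", ""))
    odd <- !valid & !na_lit
    if (any(odd))
      warning(sprintf("%d non-numeric sample row(s) masked invalid (first at body row %d)",
                      sum(odd), which(odd)[1]))
    m[!valid, ] <- 0
  }
  acc_recording(m / 64, start, rate[1], valid_mask = valid, range_g = range_g)
}

#' Write an Empatica-E4-dialect ACC CSV
#'
#' Samples are converted to integer counts (64 counts = 1 g, rounded to the
#' nearest count); invalid samples are written as `NA` rows so the grid and
#' the validity mask round-trip.
#'
#' @param rec an [acc_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_e4_acc_csv <- function(rec, path) {
  counts <- round(rec$samples * 64)
  counts[!rec$valid_mask, ] <- NA
  epoch <- format(as.numeric(rec$start_time), scientific = FALSE)
  writeLines(c(paste(rep(epoch, 3), collapse = ","),
               paste(rep(sprintf("%.6f", rec$sample_rate_hz), 3), collapse = ",")),
             path)
  if (nrow(counts))
    data.table::fwrite(data.table::as.data.table(counts), path,
                       col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a generic timestamped acceleration CSV
#'
#' Reads a long-format CSV with a timestamp column and three axis columns,
#' and snaps the rows onto the uniform grid implied by `sample_rate_hz`:
#' each row is assigned to the nearest grid point; grid points with no row
#' within half a sample period are masked invalid. Units may be g or E4
#' counts (64 counts = 1 g).
#'
#' @param path path to the CSV file.
#' @param schema named list describing the dialect: `time` (column name,
#'   ISO-8601 with zone or numeric epoch seconds), `x`, `y`, `z` column
#'   names, and `units` (`"g"` or `"counts"`).
#' @param sample_rate_hz target grid rate; the grid is anchored at the
#'   first timestamp rounded down to a whole second.
#' @param tz timezone for the resulting recording.
#' @param range_g full-scale range in g.
#' @return an [acc_recording()].
#' @export
read_acc_csv <- function(path,
                         schema = list(time = "time", x = "x", y = "y",
                                       z = "z", units = "g"),
                         sample_rate_hz = 32, tz = "UTC", range_g = 2) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path)
  need <- unlist(schema[c("time", "x", "y", "z")])
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tcol <- dt[[schema$time]]
  tsec <- if (is.numeric(tcol)) as.numeric(tcol) else
    as.numeric(as.POSIXct(as.character(tcol), tz = tz))
  if (anyNA(tsec)) stop("unparseable timestamps in column ", schema$time)
  dup <- duplicated(tsec)
  if (any(dup))
    stop("duplicate timestamps: ",
         paste(utils::head(format(tsec[dup], digits = 15), 5), collapse = ", "))
  ord <- order(tsec)
  tsec <- tsec[ord]
  m <- cbind(dt[[schema$x]], dt[[schema$y]], dt[[schema$z]])[ord, , drop = FALSE]
  if (identical(schema$units, "counts")) m <- m / 64
  t0 <- floor(tsec[1])
  idx <- round((tsec - t0) * sample_rate_hz)
  off <- abs((tsec - t0) - idx / sample_rate_hz)
  keep <- off <= (0.5 / sample_rate_hz) + 1e-9
  idx <- idx[keep] + 1L
  m <- m[keep, , drop = FALSE]
  keep2 <- !duplicated(idx)            # two rows snapping to one grid point
  idx <- idx[keep2]; m <- m[keep2, , drop = FALSE]
  n <- max(idx)
  out <- matrix(0, n, 3)
  valid <- rep(FALSE, n)
  out[idx, ] <- m
  valid[idx] <- TRUE
  acc_recording(out, as.POSIXct(t0, origin = "1970-01-01", tz = tz),
                sample_rate_hz, valid_mask = valid, range_g = range_g)
}

#' Write a generic timestamped acceleration CSV
#'
#' One row per valid grid sample, epoch-seconds timestamps at full double
#' precision, values in g. Together with [read_acc_csv()] this round-trips
#' samples and validity mask losslessly (to well below 1e-9 g).
#'
#' @param rec an [acc_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acc_csv <- function(rec, path) {
  n <- nrow(rec$samples)
  keep <- rec$valid_mask
  tsec <- as.numeric(rec$start_time) + (seq_len(n) - 1) / rec$sample_rate_hz
  dt <- data.table::data.table(
    time = tsec[keep],
    x = rec$samples[keep, 1], y = rec$samples[keep, 2],
    z = rec$samples[keep, 3])
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read an attack event log from CSV or JSON
#'
#' Expects the fields `onset`, `end` (ISO-8601 with zone, or epoch seconds),
#' `intensity` (1-5), `treatments` (`;`-separated labels) and `effective`,
#' plus `study_start`/`study_end` (JSON: top-level keys; CSV: taken from the
#' extremes of the events when absent as attributes). Records are validated
#' individually; a failing record is reported with its index.
#'
#' @param path path to a `.csv` or `.json` event log.
#' @param tz timezone for timestamp interpretation.
#' @param study_start,study_end optional `POSIXct` overrides of the study
#'   period (required for CSV when the log should extend beyond the events).
#' @return an [event_log()].
#' @export
read_event_log <- function(path, tz = "UTC",
                           study_start = NULL, study_end = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  parse_time <- function(x) {
    if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = tz))
    out <- as.POSIXct(as.character(x), tz = tz,
                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                     "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    out
  }
  if (is_json) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(j$events)
    if (is.null(study_start) && !is.null(j$study_start))
      study_start <- parse_time(j$study_start)
    if (is.null(study_end) && !is.null(j$study_end))
      study_end <- parse_time(j$study_end)
  } else {
    df <- as.data.frame(data.table::fread(path))
  }
  events <- list()
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      ev <- try(attack_event(
        onset = parse_time(df$onset[i]), end = parse_time(df$end[i]),
        intensity = df$intensity[i],
        treatments = if (is.null(df$treatments) || is.na(df$treatments[i]) ||
                         !nzchar(df$treatments[i])) "none" else
          strsplit(as.character(df$treatments[i]), ";", fixed = TRUE)[[1]],
        effective = if (is.null(df$effective)) NA else
          as.logical(df$effective[i])), silent = TRUE)
      if (inherits(ev, "try-error"))
        stop(sprintf("invalid event record %d: %s", i,
                     conditionMessage(attr(ev, "condition"))))
      events[[length(events) + 1L]] <- ev
    }
  }
  if (is.null(study_start) || is.null(study_end)) {
    if (!length(events))
      stop("study_start/study_end required when the event log is empty")
    ons <- do.call(c, lapply(events, `[[`, "onset"))
    ens <- do.call(c, lapply(events, `[[`, "end"))
    if (is.null(study_start)) study_start <- min(ons)
    if (is.null(study_end)) study_end <- max(ens) + 60
  }
  event_log(events, study_start, study_end)
}

#' Write an event log to CSV or JSON
#'
#' @param log an [event_log()].
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")
  df$onset <- iso(df$onset); df$end <- iso(df$end)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(study_start = iso(log$study_start),
           study_end = iso(log$study_end), events = df),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}
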