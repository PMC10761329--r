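#' @importFrom stats quantile rnorm rgeom runif var sd median pnorm psignrank setNames
#' @importFrom utils head tail
NULL

# Internal time helpers. All times are timezone-aware POSIXct; wall-clock
# rules (nighttime window, day-type) are evaluated in the recording's zone.

secs_between <- function(a, b) as.numeric(difftime(b, a, units = "secs"))

#' @keywords internal
assert_posixct <- function(x, what) {
  if (!inherits(x, "POSIXct")) stop(what, " must be a POSIXct datetime", call. = FALSE)
  invisible(x)
}

# seconds since local midnight of a wall-clock time
clock_secs <- function(t) {
  lt <- as.POSIXlt(t)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

local_date <- function(t) as.Date(format(t, "%Y-%m-%d"))

# rebuild a POSIXct on `date` with the wall-clock offset `secs` (DST-safe:
# goes through the textual wall-clock representation); offsets outside
# [0, 86400) roll the date
at_clock <- function(date, secs, tz) {
  shift <- secs %/% 86400
  date <- date + shift
  secs <- secs - shift * 86400
  h <- secs %/% 3600; m <- (secs %% 3600) %/% 60; s <- round(secs %% 60)
  as.POSIXct(sprintf("%s %02d:%02d:%02d", format(date), h, m, s), tz = tz)
}

is_weekend <- function(t, weekend_days = c("Saturday", "Sunday")) {
  weekdays(t, abbreviate = FALSE) %in% weekend_days
}

#' Belgian public holidays
#'
#' Fixed-date holidays plus the Easter-derived ones (Easter Monday,
#' Ascension, Whit Monday), computed with the anonymous Gregorian algorithm.
#' Useful as the `holiday_dates` entry of [calendar_config()].
#'
#' @param years integer vector of calendar years.
#' @return a `Date` vector, sorted.
#' @export
belgian_holidays <- function(years) {
  easter <- function(y) {
    a <- y %% 19; b <- y %/% 100; c <- y %% 100
    d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
    g <- (b - f + 1) %/% 3
    h <- (19 * a + b - d - g + 15) %% 30
    i <- c %/% 4; k <- c %% 4
    l <- (32 + 2 * e + 2 * i - h - k) %% 7
    m <- (a + 11 * h + 22 * l) %/% 451
    month <- (h + l - 7 * m + 114) %/% 31
    day <- ((h + l - 7 * m + 114) %% 31) + 1
    as.Date(sprintf("%d-%02d-%02d", y, month, day))
  }
  out <- lapply(years, function(y) {
    e <- easter(y)
    c(as.Date(sprintf(c("%d-01-01", "%d-05-01", "%d-07-21", "%d-08-15",
                        "%d-11-01", "%d-11-11", "%d-12-25"), y)),
      e + 1L, e + 39L, e + 50L)
  })
  sort(unique(do.call(c, out)))
}
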