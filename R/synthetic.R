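#' Default diurnal state-probability profile
#'
#' Per-hour probabilities over the four latent activity states
#' (rest, low, moderate, high). Night hours (23:00-07:00) are dominated by
#' rest; waking hours carry the mixed activity typical of wrist-worn
#' recordings; the 07:00 and 22:00 hours interpolate between the two.
#'
#' @return a 24 x 4 matrix, rows = hour of day 0-23, rows sum to 1.
#' @export
default_diurnal_profile <- function() {
  night <- c(rest = 0.88, low = 0.095, moderate = 0.015, high = 0.01)
  day <- c(rest = 0.15, low = 0.35, moderate = 0.30, high = 0.20)
  edge <- (night + day) / 2
  prof <- matrix(NA_real_, 24, 4, dimnames = list(NULL, names(night)))
  for (h in 0:23) {
    prof[h + 1, ] <-
      if (h >= 23 || h < 7) night else if (h == 7 || h == 22) edge else day
  }
  prof
}

#' Configuration of the synthetic-recording generator
#'
#' Defines a multi-day wrist-accelerometer study: a minute-resolution
#' semi-Markov chain over four latent activity states (rest, low, moderate,
#' high) with diurnal state weights and geometric bout dwell times; each
#' bout carries a lognormal intensity multiplier so the per-minute AI
#' distribution is continuous. Emitted samples are a slowly drifting unit
#' gravity vector plus zero-mean Gaussian noise with the bout's SD. Attacks
#' are embedded as windows where the probability of the "high" state is
#' multiplied by `attack_effect` (optionally from `preictal_effect_minutes`
#' before onset): a multiplier below 1 suppresses intense movement during
#' the attack, above 1 produces agitation, and exactly 1 leaves the process
#' untouched (the null). Cluster-headache attacks arrive in bouts, so the
#' generator places several attacks per "bout day" by default, leaving
#' attack-free days available as matched comparison days.
#'
#' @param study_start `POSIXct` start (whole midnight recommended).
#' @param study_days length of the recording in days (default 21).
#' @param sample_rate_hz sampling rate (default 32).
#' @param state_sds per-state acceleration noise SD in g.
#' @param state_dwell_minutes per-state mean bout duration in minutes.
#' @param diurnal_profile 24 x 4 matrix of per-hour time-occupancy
#'   fractions over the states (rows sum to 1); bout-state draw weights
#'   are occupancy divided by mean dwell.
#' @param n_attacks number of embedded attacks.
#' @param attack_duration_mean_min,attack_duration_sd_min attack duration
#'   distribution in minutes (Gaussian truncated to 15-180, the
#'   cluster-headache range; defaults 37 and 25).
#' @param attack_effect multiplier on the "high"-state weight inside the
#'   effect window (default 1 = null).
#' @param preictal_effect_minutes minutes before onset the effect already
#'   applies (default 30).
#' @param attack_days optional integer vector of study days (1-based) to
#'   place attacks on; default: `ceiling(n_attacks / 3)` randomly chosen
#'   bout days, about three attacks per bout day.
#' @param attack_onset_hours wall-clock hour range for onsets (default
#'   `c(8, 20)`, i.e., daytime-biased; widen to force nighttime attacks).
#' @param attack_windows optional data.frame (`onset`, `end` `POSIXct`)
#'   fixing the attack windows exactly; overlapping windows are rejected.
#' @param bout_intensity_sdlog lognormal sdlog of the per-bout intensity
#'   multiplier (default 0.35).
#' @param gravity_drift_sd per-minute SD of the gravity orientation random
#'   walk, in g (default 0.02).
#' @param gap_rate expected fraction of samples lost to streaming dropouts
#'   (bursty; default 0).
#' @param offbody_segments optional data.frame (`start_hour` offset from
#'   study start, `duration_min`) of off-body windows: frozen orientation,
#'   near-zero noise (`offbody_noise_sd`).
#' @param offbody_noise_sd noise SD during off-body segments (default
#'   0.001 g).
#' @param holiday_dates `Date` vector forwarded to the calendar config of
#'   downstream analyses.
#' @param range_g accelerometer range (default 2).
#' @param seed integer seed; same seed + same config give byte-identical
#'   output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(study_start = as.POSIXct("2024-04-08 00:00:00",
                                                  tz = "Europe/Brussels"),
                         study_days = 21, sample_rate_hz = 32,
                         state_sds = c(rest = 0.005, low = 0.03,
                                       moderate = 0.10, high = 0.30),
                         state_dwell_minutes = c(rest = 20, low = 5,
                                                 moderate = 3, high = 1),
                         diurnal_profile = default_diurnal_profile(),
                         n_attacks = 10,
                         attack_duration_mean_min = 37,
                         attack_duration_sd_min = 25,
                         attack_effect = 1.0,
                         preictal_effect_minutes = 30,
                         attack_days = NULL,
                         attack_onset_hours = c(8, 20),
                         attack_windows = NULL,
                         bout_intensity_sdlog = 0.35,
                         gravity_drift_sd = 0.02,
                         gap_rate = 0,
                         offbody_segments = NULL,
                         offbody_noise_sd = 0.001,
                         holiday_dates = as.Date(character()),
                         range_g = 2,
                         seed = 1L) {
  assert_posixct(study_start, "study_start")
  stopifnot(study_days >= 1, sample_rate_hz >= 1,
            all(state_sds > 0), all(state_dwell_minutes > 0),
            attack_effect >= 0, preictal_effect_minutes >= 0,
            bout_intensity_sdlog >= 0, gravity_drift_sd >= 0,
            gap_rate >= 0, gap_rate < 1, offbody_noise_sd > 0,
            n_attacks >= 0)
  diurnal_profile <- as.matrix(diurnal_profile)
  stopifnot(nrow(diurnal_profile) == 24, ncol(diurnal_profile) == 4,
            all(diurnal_profile >= 0),
            all(abs(rowSums(diurnal_profile) - 1) < 1e-8))
  if (!is.null(attack_windows)) {
    stopifnot(is.data.frame(attack_windows),
              all(c("onset", "end") %in% names(attack_windows)))
    check_attack_overlaps(attack_windows)
  }
  structure(list(
    study_start = study_start, study_days = study_days,
    sample_rate_hz = as.integer(sample_rate_hz),
    state_sds = state_sds, state_dwell_minutes = state_dwell_minutes,
    diurnal_profile = diurnal_profile, n_attacks = as.integer(n_attacks),
    attack_duration_mean_min = attack_duration_mean_min,
    attack_duration_sd_min = attack_duration_sd_min,
    attack_effect = attack_effect,
    preictal_effect_minutes = preictal_effect_minutes,
    attack_days = attack_days, attack_onset_hours = attack_onset_hours,
    attack_windows = attack_windows,
    bout_intensity_sdlog = bout_intensity_sdlog,
    gravity_drift_sd = gravity_drift_sd, gap_rate = gap_rate,
    offbody_segments = offbody_segments,
    offbody_noise_sd = offbody_noise_sd,
    holiday_dates = as.Date(holiday_dates), range_g = range_g,
    seed = as.integer(seed)),
    class = "synth_config")
}

check_attack_overlaps <- function(w) {
  if (nrow(w) < 2L) return(invisible(w))
  ord <- order(w$onset)
  on <- as.numeric(w$onset)[ord]; en <- as.numeric(w$end)[ord]
  bad <- which(on[-1] < en[-length(en)])
  if (length(bad))
    stop("overlapping attack windows: ",
         paste(sprintf("[%s .. %s] vs [%s .. %s]",
                       format(w$onset[ord][bad], "%Y-%m-%d %H:%M"),
                       format(w$end[ord][bad], "%H:%M"),
                       format(w$onset[ord][bad + 1], "%Y-%m-%d %H:%M"),
                       format(w$end[ord][bad + 1], "%H:%M")),
               collapse = "; "))
  invisible(w)
}

place_attacks <- function(config, n_min) {
  if (!is.null(config$attack_windows)) {
    w <- config$attack_windows[order(config$attack_windows$onset), ,
                               drop = FALSE]
    return(data.frame(
      onset_min = round(secs_between(config$study_start, w$onset) / 60),
      dur_min = round(secs_between(w$onset, w$end) / 60)))
  }
  n <- config$n_attacks
  if (n == 0L) return(data.frame(onset_min = integer(), dur_min = integer()))
  days <- config$attack_days
  if (is.null(days))
    days <- sort(sample(config$study_days, min(config$study_days,
                                               ceiling(n / 3))))
  day_of <- days[1 + (seq_len(n) - 1) %% length(days)]
  h0 <- config$attack_onset_hours[1] * 60
  h1 <- config$attack_onset_hours[2] * 60
  draw_dur <- function() {
    for (k in 1:1000) {
      d <- round(rnorm(1, config$attack_duration_mean_min,
                       config$attack_duration_sd_min))
      if (d >= 15 && d <= 180) return(d)
    }
    stop("could not draw an attack duration in 15..180 min")
  }
  onset_min <- integer(n); dur_min <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:500) {
      dur <- draw_dur()
      o <- (day_of[i] - 1) * 1440 + floor(runif(1, h0, h1 - dur))
      # 15-min guard band between attacks
      if (i == 1L || all(o >= onset_min[seq_len(i - 1)] +
                           dur_min[seq_len(i - 1)] + 15 |
                         o + dur + 15 <= onset_min[seq_len(i - 1)])) {
        onset_min[i] <- o; dur_min[i] <- dur; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping attacks on ",
                  length(days), " day(s); give more attack_days")
  }
  ord <- order(onset_min)
  out <- data.frame(onset_min = onset_min[ord], dur_min = dur_min[ord])
  if (any(out$onset_min < 0) || any(out$onset_min + out$dur_min > n_min))
    stop("attack window falls outside the study period")
  out
}

#' Generate a synthetic recording, event log and ground truth
#'
#' Runs the generative model of [synth_config()]: latent per-minute states,
#' drifting gravity, state-dependent noise, embedded attack effects,
#' off-body segments, then bursty streaming gaps. All randomness flows from
#' `config$seed`; identical configs give byte-identical output.
#'
#' @param config a [synth_config()].
#' @return list with `recording` ([acc_recording()]), `events`
#'   ([event_log()]) and `truth` (list: `attacks` data.frame,
#'   `state_per_minute`, `bout_multiplier_per_minute`, `gap_mask`,
#'   `offbody_mask`, `effect_windows`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  r <- config$sample_rate_hz
  spm <- 60L * r
  n_min <- config$study_days * 1440L
  n <- n_min * spm
  tz <- attr(config$study_start, "tzone")

  attacks <- place_attacks(config, n_min)
  n_att <- nrow(attacks)
  effect_min <- rep(FALSE, n_min)
  pre <- config$preictal_effect_minutes
  if (n_att) for (i in seq_len(n_att)) {
    a0 <- max(1L, attacks$onset_min[i] - pre + 1L)
    a1 <- attacks$onset_min[i] + attacks$dur_min[i]
    effect_min[a0:a1] <- TRUE
  }

  # hour-of-day per minute, on the local wall clock
  minute_times <- config$study_start + (seq_len(n_min) - 1) * 60
  hour_of_min <- as.POSIXlt(minute_times)$hour

  # latent semi-Markov states with per-bout lognormal intensity
  state <- integer(n_min)
  mult <- numeric(n_min)
  dwell <- config$state_dwell_minutes
  prof <- config$diurnal_profile
  t <- 1L
  while (t <= n_min) {
    # profile rows are time-occupancy fractions; a bout's state is drawn
    # with weight occupancy / mean dwell so occupancy comes out right
    occ <- prof[hour_of_min[t] + 1L, ]
    if (effect_min[t] && config$attack_effect != 1) {
      # suppressed (or added) high-intensity time is exchanged with rest:
      # a patient holding still during an attack is resting, not moving
      # moderately; the exchange keeps the occupancy vector normalized
      d <- occ[4] * (config$attack_effect - 1)
      d <- max(-occ[4], min(d, occ[1] - 1e-6))
      occ[4] <- occ[4] + d
      occ[1] <- occ[1] - d
    }
    w <- occ / dwell
    s <- sample.int(4L, 1L, prob = w)
    d <- 1L + rgeom(1L, 1 / dwell[s])
    b_mult <- exp(rnorm(1L, 0, config$bout_intensity_sdlog))
    t1 <- min(n_min, t + d - 1L)
    state[t:t1] <- s
    mult[t:t1] <- b_mult
    t <- t1 + 1L
  }

  # gravity: per-minute orientation random walk, interpolated to seconds
  # (gravity is constant within each 1-s AI window either way, and the AI
  # is location-invariant, so sub-second interpolation adds nothing)
  gnode <- matrix(0, n_min, 3)
  gnode[1, ] <- rnorm(3)
  steps <- matrix(rnorm(3 * (n_min - 1), 0, config$gravity_drift_sd),
                  n_min - 1, 3)
  for (j in 1:3) gnode[, j] <- cumsum(c(gnode[1, j], steps[, j]))
  gnode <- gnode / sqrt(rowSums(gnode^2))
  n_sec <- n_min * 60L
  node_sec <- (seq_len(n_min) - 1L) * 60L + 1L
  gsec <- matrix(0, n_sec, 3)
  for (j in 1:3)
    gsec[, j] <- stats::approx(node_sec, gnode[, j], xout = seq_len(n_sec),
                               rule = 2)$y
  gsec <- gsec / sqrt(rowSums(gsec^2))

  samples <- rnorm(3 * n)
  dim(samples) <- c(n, 3)
  samples <- samples * rep(config$state_sds[state] * mult, each = spm)
  for (j in 1:3) samples[, j] <- samples[, j] + rep(gsec[, j], each = r)

  # off-body segments: frozen orientation, near-zero noise
  offbody_mask <- rep(FALSE, n)
  if (!is.null(config$offbody_segments) && nrow(config$offbody_segments)) {
    for (i in seq_len(nrow(config$offbody_segments))) {
      s0 <- round(config$offbody_segments$start_hour[i] * 3600 * r) + 1L
      s1 <- s0 + round(config$offbody_segments$duration_min[i] * 60 * r) - 1L
      s0 <- max(1L, s0); s1 <- min(n, s1)
      if (s1 < s0) next
      frozen <- gsec[(s0 - 1L) %/% r + 1L, ]
      k <- s1 - s0 + 1L
      samples[s0:s1, ] <- rep(frozen, each = k) +
        matrix(rnorm(3 * k, 0, config$offbody_noise_sd), k, 3)
      offbody_mask[s0:s1] <- TRUE
    }
  }
  rng <- range(samples)
  if (rng[2] > config$range_g) samples[samples > config$range_g] <- config$range_g
  if (rng[1] < -config$range_g) samples[samples < -config$range_g] <- -config$range_g

  colnames(samples) <- c("x", "y", "z")
  rec <- structure(
    list(samples = samples, start_time = config$study_start,
         sample_rate_hz = r, valid_mask = rep(TRUE, n),
         on_body_mask = rep(TRUE, n), range_g = config$range_g),
    class = "acc_recording")
  gap_mask <- rep(FALSE, n)
  if (config$gap_rate > 0) {
    rec <- inject_missingness(rec, config$gap_rate,
                              seed = (config$seed %% 1000000L) * 1009L + 7L)
    gap_mask <- !rec$valid_mask
  }

  events <- list()
  if (n_att) {
    treat_pool <- c(oxygen = 0.5, none = 0.15, unspecified = 0.1,
                    sumatriptan_sc = 0.1, zolmitriptan_nasal = 0.05,
                    combination_analgesic = 0.1)
    for (i in seq_len(n_att)) {
      onset <- config$study_start + attacks$onset_min[i] * 60
      end <- onset + attacks$dur_min[i] * 60
      events[[i]] <- attack_event(
        onset, end, intensity = sample(2:5, 1),
        treatments = sample(names(treat_pool), 1, prob = treat_pool),
        effective = runif(1) < 0.7)
    }
  }
  log <- event_log(events, config$study_start,
                   config$study_start + config$study_days * 86400)

  truth <- list(
    attacks = data.frame(
      onset = config$study_start + attacks$onset_min * 60,
      end = config$study_start + (attacks$onset_min + attacks$dur_min) * 60),
    state_per_minute = state,
    bout_multiplier_per_minute = mult,
    gap_mask = gap_mask,
    offbody_mask = offbody_mask,
    effect_minutes = effect_min)
  list(recording = rec, events = log, truth = truth)
}

#' Inject bursty streaming gaps
#'
#' Masks samples invalid in geometric-length bursts (mean two seconds)
#' alternating with geometric valid runs sized so the long-run invalid
#' fraction equals `gap_rate`. Deterministic given `seed`.
#'
#' @param rec an [acc_recording()].
#' @param gap_rate target invalid fraction, in `[0, 1)`.
#' @param seed integer seed.
#' @return the recording with its `valid_mask` updated (existing invalid
#'   samples stay invalid).
#' @export
inject_missingness <- function(rec, gap_rate, seed) {
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  if (gap_rate == 0) return(rec)
  n <- nrow(rec$samples)
  mean_gap <- 2 * rec$sample_rate_hz              # two-second mean bursts
  mean_ok <- mean_gap * (1 - gap_rate) / gap_rate
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  total <- 0L; lens <- integer(0); vals <- logical(0)
  invalid <- runif(1) < gap_rate                  # random starting phase
  while (total < n) {
    batch <- 256L
    l_ok <- 1L + rgeom(batch, 1 / mean_ok)
    l_gap <- 1L + rgeom(batch, 1 / mean_gap)
    if (invalid) {
      lens <- c(lens, rbind(l_gap, l_ok))
      vals <- c(vals, rep(c(FALSE, TRUE), batch))
    } else {
      lens <- c(lens, rbind(l_ok, l_gap))
      vals <- c(vals, rep(c(TRUE, FALSE), batch))
    }
    invalid <- FALSE
    total <- total + sum(l_ok) + sum(l_gap)
  }
  mask <- rep(vals, lens)[seq_len(n)]
  rec$valid_mask <- rec$valid_mask & mask
  rec
}
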