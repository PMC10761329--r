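# a flat all-valid recording spanning `days` from a Monday; cheap to build
flat_recording <- function(days = 21, rate = 1,
                           start = bru_time("2024-04-08 00:00:00")) {
  n <- days * 86400 * rate
  acc_recording(matrix(rep(c(0, 0, 1), each = n), n, 3), start, rate)
}

attack_at <- function(onset, end, intensity = 3, treatments = "oxygen")
  attack_event(bru_time(onset), bru_time(end), intensity, treatments)

test_that("data ratio counts valid on-body samples, boundary inclusive", {
  rec <- flat_recording(2, rate = 4)
  s <- bru_time("2024-04-08 10:00:00"); e <- bru_time("2024-04-08 11:00:00")
  expect_identical(data_ratio(rec, s, e), 1)

  rec$valid_mask[(10 * 3600 * 4 + 1):(10 * 3600 * 4 + 3600)] <- FALSE
  expect_equal(data_ratio(rec, s, e), 0.75)
  expect_gte(data_ratio(rec, s, e), 0.75)   # exactly 25% missing passes

  rec$on_body_mask[(10 * 3600 * 4 + 1):(11 * 3600 * 4)] <- FALSE
  expect_identical(data_ratio(rec, s, e), 0)
  expect_error(data_ratio(rec, s, bru_time("2024-04-11 00:00:00")), "outside")
})

test_that("daytime rule excludes any overlap with the 23:00-07:30 window", {
  cal <- calendar_config()
  expect_true(is_daytime(attack_at("2024-04-09 10:00:00", "2024-04-09 10:40:00"), cal))
  expect_false(is_daytime(attack_at("2024-04-09 07:00:00", "2024-04-09 07:45:00"), cal))
  expect_false(is_daytime(attack_at("2024-04-09 22:30:00", "2024-04-09 23:10:00"), cal))
  expect_true(is_daytime(attack_at("2024-04-09 07:30:00", "2024-04-09 08:00:00"), cal))
  # a multi-hour window crossing a full night
  expect_false(is_daytime(attack_at("2024-04-09 05:10:00", "2024-04-09 07:10:00"), cal))
})

test_that("matched candidates equal a brute-force calendar enumeration", {
  rec <- flat_recording(21)
  a <- attack_at("2024-04-09 14:00:00", "2024-04-09 14:40:00")   # Tuesday
  log <- event_log(list(a), rec$start_time, rec$start_time + 21 * 86400)
  cand <- find_non_ch_intervals(a, log, rec)
  oracle <- sort(brute_candidates(a, log, rec))
  expect_identical(sort(as.numeric(cand$start)), oracle)
  # 15 weekdays in 21 days, minus the attack day and its two neighbours
  expect_equal(nrow(cand), 12L)
  expect_true(all(cand$data_ratio == 1))
  expect_true(all(format(cand$start, "%H:%M") == "14:00"))
})

test_that("day-type matching keeps weekend attacks on weekend days", {
  rec <- flat_recording(21)
  a <- attack_at("2024-04-13 14:00:00", "2024-04-13 14:40:00")   # Saturday
  log <- event_log(list(a), rec$start_time, rec$start_time + 21 * 86400)
  cand <- find_non_ch_intervals(a, log, rec)
  expect_true(all(format(cand$start, "%u") %in% c("6", "7")))
  expect_identical(sort(as.numeric(cand$start)),
                   sort(brute_candidates(a, log, rec)))
})

test_that("holiday candidate days are excluded", {
  rec <- flat_recording(21)
  a <- attack_at("2024-04-09 14:00:00", "2024-04-09 14:40:00")
  log <- event_log(list(a), rec$start_time, rec$start_time + 21 * 86400)
  hol <- as.Date("2024-04-17")                                   # a Wednesday
  cand <- find_non_ch_intervals(a, log, rec,
                                calendar_config(holiday_dates = hol))
  expect_false(any(format(cand$start, "%Y-%m-%d") == "2024-04-17"))
  expect_equal(nrow(cand), 11L)
})

test_that("the 24-h exclusion is symmetric over all attack boundaries", {
  rec <- flat_recording(21)
  atk <- list(
    attack_at("2024-04-09 14:00:00", "2024-04-09 14:40:00"),
    attack_at("2024-04-12 09:30:00", "2024-04-12 10:15:00"),
    attack_at("2024-04-18 16:00:00", "2024-04-18 17:30:00"))
  log <- event_log(atk, rec$start_time, rec$start_time + 21 * 86400)
  bounds <- unlist(lapply(atk, function(a) c(as.numeric(a$onset),
                                             as.numeric(a$end))))
  for (a in atk) {
    cand <- find_non_ch_intervals(a, log, rec)
    for (i in seq_len(nrow(cand))) {
      cs <- as.numeric(cand$start[i]); ce <- as.numeric(cand$end[i])
      for (b in bounds) {
        inside <- b >= cs && b < ce
        expect_false(inside)
        expect_gte(min(abs(cs - b), abs(ce - b)), 86400)
      }
    }
  }
})

test_that("onset-relative bins tile -3h..+3h around onset", {
  a <- attack_at("2024-04-09 12:00:00", "2024-04-09 12:40:00")
  bins <- onset_relative_bins(a)
  expect_identical(bins$bin_id,
                   c("-3h..-1h", "-1h..-30m", "-30m..0", "0..+30m",
                     "+30m..+1h", "+1h..+2h", "+2h..+3h"))
  expect_equal(format(bins$start, "%H:%M"),
               c("09:00", "11:00", "11:30", "12:00", "12:30", "13:00", "14:00"))
  expect_equal(format(bins$end, "%H:%M"),
               c("11:00", "11:30", "12:00", "12:30", "13:00", "14:00", "15:00"))
})

test_that("pooling concatenates valid minutes and is order-invariant", {
  rec <- flat_recording(7, rate = 4)
  ai <- compute_ai(rec)
  cand <- data.frame(
    start = bru_time(c("2024-04-09 10:00:00", "2024-04-11 10:00:00")),
    end = bru_time(c("2024-04-09 10:40:00", "2024-04-11 10:40:00")),
    data_ratio = 1)
  pooled <- pool_non_ch(cand, ai)
  expect_length(pooled, 80L)
  flipped <- pool_non_ch(cand[2:1, ], ai)
  expect_identical(percentile_features(pooled), percentile_features(flipped))
  expect_error(pool_non_ch(cand[0, ], ai), "not analyzable")
})

test_that("eligibility is monotone in data", {
  cfg <- synth_config(study_days = 7, sample_rate_hz = 2, n_attacks = 8,
                      attack_days = c(1, 2, 6), gap_rate = 0.3, seed = 31)
  sim <- generate_recording(cfg)
  rec <- sim$recording
  e0 <- attack_eligibility(sim$events, rec)
  rec2 <- rec
  bad <- which(!rec2$valid_mask)
  set.seed(1)
  rec2$valid_mask[sample(bad, round(0.5 * length(bad)))] <- TRUE
  e1 <- attack_eligibility(sim$events, rec2)
  was <- e0$ledger$status == "eligible"
  expect_true(all(e1$ledger$status[was] == "eligible"))
})
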