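test_that("identical config and seed give byte-identical output", {
  cfg <- synth_config(study_days = 2, sample_rate_hz = 4, n_attacks = 3,
                      attack_days = 1, gap_rate = 0.1,
                      offbody_segments = data.frame(start_hour = 30,
                                                    duration_min = 40),
                      seed = 77)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$recording$valid_mask, b$recording$valid_mask)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$truth, b$truth)
})

test_that("a degenerate config yields a clean recording and empty log", {
  cfg <- synth_config(study_days = 1, sample_rate_hz = 4, n_attacks = 0,
                      gap_rate = 0, seed = 2)
  sim <- generate_recording(cfg)
  expect_true(all(sim$recording$valid_mask))
  expect_true(all(sim$recording$on_body_mask))
  expect_equal(length(sim$events), 0L)
  expect_equal(nrow(sim$truth$attacks), 0L)
})

test_that("attack windows are in-period, sorted, non-overlapping", {
  for (seed in 1:5) {
    cfg <- synth_config(study_days = 7, sample_rate_hz = 2, n_attacks = 12,
                        attack_days = 1:4, seed = seed)
    sim <- generate_recording(cfg)
    df <- sim$truth$attacks
    expect_equal(nrow(df), 12L)
    expect_true(all(diff(as.numeric(df$onset)) > 0))
    expect_true(all(as.numeric(df$end)[-12] <= as.numeric(df$onset)[-1]))
    expect_true(all(as.numeric(df$onset) >= as.numeric(cfg$study_start)))
    expect_true(all(as.numeric(df$end) <=
                    as.numeric(cfg$study_start) + 7 * 86400))
    durs <- (as.numeric(df$end) - as.numeric(df$onset)) / 60
    expect_true(all(durs >= 15 & durs <= 180))
  }
})

test_that("explicitly overlapping attack windows are rejected by name", {
  win <- data.frame(
    onset = bru_time(c("2024-04-09 10:00:00", "2024-04-09 10:30:00")),
    end = bru_time(c("2024-04-09 11:00:00", "2024-04-09 11:30:00")))
  expect_error(synth_config(attack_windows = win),
               "overlapping attack windows.*10:00")
})

test_that("ground-truth masks are consistent with the emitted recording", {
  cfg <- synth_config(study_days = 1, sample_rate_hz = 8, n_attacks = 0,
                      gap_rate = 0.2,
                      offbody_segments = data.frame(start_hour = 5,
                                                    duration_min = 90),
                      seed = 13)
  sim <- generate_recording(cfg)
  expect_identical(sim$truth$gap_mask, !sim$recording$valid_mask)
  off <- sim$truth$offbody_mask
  seg <- sim$recording$samples[off, ]
  # off-body: fixed orientation, rest-level variance
  expect_lt(max(apply(seg, 2, sd)), 0.004)
  expect_equal(sqrt(sum(colMeans(seg)^2)), 1, tolerance = 0.01)
})

test_that("suppression lowers in-attack activity in every seed", {
  for (seed in 1:8) {
    cfg <- synth_config(study_days = 2, sample_rate_hz = 4, n_attacks = 3,
                        attack_days = 1, attack_effect = 0.2, seed = seed)
    sim <- generate_recording(cfg)
    ai <- compute_ai(sim$recording)
    em <- sim$truth$effect_minutes
    hrs <- as.POSIXlt(ai$per_minute$time)$hour
    day <- hrs >= 8 & hrs < 22
    inside <- ai$per_minute$ai[em & day]
    outside <- ai$per_minute$ai[!em & day]
    expect_lt(mean(inside, na.rm = TRUE), mean(outside, na.rm = TRUE))
  }
})

test_that("a null attack effect leaves the in-attack AI distribution unchanged", {
  # per-minute AI is serially dependent (bout structure), so a two-sample
  # test treating minutes as iid is invalid; the exchangeable unit is the
  # per-seed delta between the attack window and the same clock window on
  # the next day, which must be symmetric around zero under the null
  d <- vapply(1:40, function(seed) {
    cfg <- synth_config(study_days = 2, sample_rate_hz = 2, n_attacks = 2,
                        attack_days = 1, attack_effect = 1, seed = seed)
    sim <- generate_recording(cfg)
    ai <- compute_ai(sim$recording)
    a <- sim$truth$attacks
    ch <- match <- c()
    for (i in seq_len(nrow(a))) {
      ch <- c(ch, minute_values_for_test(ai, a$onset[i], a$end[i]))
      match <- c(match, minute_values_for_test(ai, a$onset[i] + 86400,
                                               a$end[i] + 86400))
    }
    median(ch) - median(match)
  }, numeric(1))
  expect_gte(sum(d > 0), 10)               # balanced signs over 40 seeds
  expect_lte(sum(d > 0), 30)
  expect_gt(wilcoxon_signed_rank(d)$p_value, 0.01)
})

test_that("injected gaps hit the target rate in geometric bursts", {
  rec <- random_recording(2000, rate = 16, seed = 5)   # 32k... samples
  expect_identical(inject_missingness(rec, 0, 1)$valid_mask, rec$valid_mask)

  big <- random_recording(62500 * 2, rate = 8, seed = 6)  # 1e6 samples
  out <- inject_missingness(big, 0.25, seed = 9)
  expect_equal(mean(!out$valid_mask), 0.25, tolerance = 0.01)
  out2 <- inject_missingness(big, 0.25, seed = 9)
  expect_identical(out$valid_mask, out2$valid_mask)
  out3 <- inject_missingness(big, 0.25, seed = 10)
  expect_false(identical(out$valid_mask, out3$valid_mask))
  expect_error(inject_missingness(big, 1, 1), "gap_rate")
})
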