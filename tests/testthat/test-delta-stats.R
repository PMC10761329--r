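test_that("percentile features use linear interpolation between order stats", {
  f <- percentile_features(c(1, 2, 3, 4))
  expect_equal(f, c(p25 = 1.75, p50 = 2.5, p75 = 3.25, p90 = 3.7))
  expect_equal(unname(percentile_features(rep(0.3, 10))), rep(0.3, 4))
  expect_error(percentile_features(c(NA, NA)), "empty")
  set.seed(3)
  for (i in 1:20) {
    f <- percentile_features(rlnorm(sample(5:200, 1)))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("deltas are zero at identity, antisymmetric, sign-faithful", {
  set.seed(4)
  x <- rlnorm(100); y <- rlnorm(120) * 0.4
  fx <- percentile_features(x); fy <- percentile_features(y)
  expect_identical(unname(delta_features(fx, fx)), rep(0, 4))
  expect_equal(delta_features(fx, fy), -delta_features(fy, fx))
  # stochastically smaller attack side gives non-positive deltas
  expect_true(all(delta_features(percentile_features(x * 0.3), fx) <= 0))
})

test_that("exact Wilcoxon matches hand-enumerated cases", {
  r <- suppressWarnings(wilcoxon_signed_rank(c(1, 2, 3, 4, 5)))
  expect_true(r$exact)
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 2 / 32)

  r <- wilcoxon_signed_rank(c(-2, 1))       # symmetric-ish, no ties
  expect_equal(r$p_value, 1)

  r <- wilcoxon_signed_rank(5)              # single pair is uninformative
  expect_equal(r$p_value, 1)

  expect_warning(r <- wilcoxon_signed_rank(c(0, 0, 0)), "no information")
  expect_equal(r$p_value, 1)
})

test_that("exact mode equals exhaustive sign-flip enumeration", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    d <- round(rlnorm(n), 6) * sample(c(-1, 1), n, replace = TRUE)
    if (any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, enum_signrank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon agrees with the reference implementation", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    d <- rnorm(n)
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  # tied magnitudes force the midrank normal approximation
  for (i in 1:25) {
    d <- sample(c(-3, -2, -1, 1, 2, 3), 30, replace = TRUE)
    ours <- wilcoxon_signed_rank(d)
    expect_false(ours$exact)
    ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the Pratt rule keeps zeros in the ranking", {
  d <- c(0, 0, 1, 2, -3, 4, 5, -6, 7)
  r <- wilcoxon_signed_rank(d, zero_method = "pratt")
  expect_equal(r$n, 7)
  expect_false(r$exact)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  # without zeros, pratt and wilcox rules coincide
  d2 <- d[d != 0]
  expect_equal(wilcoxon_signed_rank(d2, zero_method = "pratt")$statistic,
               wilcoxon_signed_rank(d2, exact = FALSE)$statistic)
})

test_that("Bonferroni uses the explicit family size with clamping", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(0.2), 0.2)        # m defaults to length = 1
  p <- c(0.001, 0.02, 0.7)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least")
  expect_true(all(bonferroni(p, m = 10) >= p))
})

test_that("a single eligible attack yields a delta row and a degenerate test", {
  win <- data.frame(onset = bru_time("2024-04-09 10:00:00"),
                    end = bru_time("2024-04-09 10:40:00"))
  cfg <- synth_config(study_days = 4, sample_rate_hz = 4,
                      attack_windows = win, seed = 17)
  sim <- generate_recording(cfg)
  run <- run_pipeline(sim$recording, sim$events, run_config())
  expect_identical(unname(run$funnel), c(1L, 1L, 1L, 1L))
  expect_equal(nrow(run$delta_table), 4L)
  expect_true(all(run$stat_report$n == 1))
  expect_true(all(run$stat_report$p_adj == 1))
})

test_that("stratified analysis restricts the test to one treatment label", {
  cfg <- synth_config(study_days = 14, sample_rate_hz = 2, n_attacks = 9,
                      attack_days = 1:3, seed = 23)
  sim <- generate_recording(cfg)
  run <- run_pipeline(sim$recording, sim$events,
                      run_config(stratify_treatment = "oxygen",
                                 onset_relative = FALSE))
  labs <- unique(run$delta_table$treatment)
  n_oxy <- sum(vapply(strsplit(run$delta_table$treatment[
    run$delta_table$percentile == "p90"], ";"),
    function(x) "oxygen" %in% x, logical(1)))
  if (n_oxy > 0) {
    expect_true(all(run$stratified$stat_report$n == n_oxy))
    expect_equal(nrow(run$stratified$delta_table), nrow(run$delta_table))
  } else {
    expect_equal(nrow(run$stratified$stat_report), 0L)
  }
})
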