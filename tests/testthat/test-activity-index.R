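make_window <- function(x, y, z) cbind(x = x, y = y, z = z)

test_that("single-window AI matches hand-computed variances", {
  # constant acceleration carries no movement
  w0 <- make_window(rep(0, 32), rep(0, 32), rep(1, 32))
  expect_identical(ai_second(w0), 0)

  # x alternating +/-0.5 g: sample variance 32*0.25/31 = 8/31, mean over
  # the three axes /3
  walt <- make_window(rep(c(0.5, -0.5), 16), rep(0, 32), rep(1, 32))
  expect_equal(ai_second(walt), sqrt((8 / 31) / 3), tolerance = 1e-12)
  expect_equal(ai_second(walt, ai_params(variance_estimator = "population_n")),
               sqrt((8 / 32) / 3), tolerance = 1e-12)
  # scalar path agrees with base var()
  expect_equal(ai_second(walt)^2 * 3,
               var(walt[, 1]) + var(walt[, 2]) + var(walt[, 3]),
               tolerance = 1e-14)

  expect_error(ai_second(walt[1:16, ]), "expected")
})

test_that("AI is location-invariant, |c|-homogeneous and axis-symmetric", {
  set.seed(42)
  for (i in 1:25) {
    w <- matrix(rnorm(96, sd = runif(1, 0.01, 0.5)), 32, 3)
    ai <- ai_second(w)
    expect_gte(ai, 0)
    shift <- sweep(w, 2, c(0.3, -0.2, 0.1), "+")
    expect_equal(ai_second(shift), ai, tolerance = 1e-12)
    cc <- runif(1, -3, 3)
    expect_equal(ai_second(w * cc), abs(cc) * ai, tolerance = 1e-10)
    expect_equal(ai_second(w[, c(3, 1, 2)]), ai, tolerance = 1e-14)
  }
})

test_that("sigma_i correction subtracts noise variance with a zero floor", {
  w <- make_window(rep(c(0.5, -0.5), 16), rep(0, 32), rep(1, 32))
  v <- (8 / 31) / 3
  p <- ai_params(sigma_i = 0.1)
  expect_equal(ai_second(w, p), sqrt(v - 0.01), tolerance = 1e-12)
  expect_identical(ai_second(w, ai_params(sigma_i = 1)), 0)
})

test_that("per-minute aggregation averages valid seconds above the floor", {
  expect_equal(ai_minute(rep(0.37, 60)), 0.37)
  expect_equal(ai_minute(0:59), 29.5)
  v <- c(rep(0.1, 29), rep(NA, 31))
  expect_identical(ai_minute(v), NA_real_)      # 29 valid < 30
  expect_equal(ai_minute(c(rep(0.1, 30), rep(NA, 30))), 0.1)
  expect_error(ai_minute(rep(1, 61)), "at most 60")
})

test_that("vectorized AI equals the naive per-window loop", {
  for (seed in 1:3) {
    rec <- random_recording(10 * 60, rate = 32, seed = seed,
                            gap_frac = if (seed > 1) 0.08 else 0)
    if (seed == 3) {
      rec$on_body_mask[1000:5000] <- FALSE
      p <- ai_params(min_valid_fraction_per_window = 0.75)
    } else p <- ai_params()
    ai <- compute_ai(rec, p)
    oracle <- naive_ai_per_second(rec, p)
    expect_identical(is.na(ai$per_second$ai), is.na(oracle))
    ok <- !is.na(oracle)
    expect_lt(max(abs(ai$per_second$ai[ok] - oracle[ok])), 1e-12)
  }
})

test_that("mean per-second AI recovers the noise SD of iid input", {
  set.seed(99)
  sigma <- 0.12
  n_sec <- 10000
  m <- matrix(rnorm(3 * n_sec * 32, sd = sigma), ncol = 3)
  rec <- acc_recording(m, bru_time("2024-04-08 00:00:00"), 32)
  ai <- compute_ai(rec)
  expect_equal(mean(ai$per_second$ai), sigma, tolerance = 0.02)
})

test_that("an all-rest recording yields small positive per-minute AI", {
  prof <- matrix(rep(c(1, 0, 0, 0), each = 24), 24, 4)
  cfg <- synth_config(study_days = 1, sample_rate_hz = 8, n_attacks = 0,
                      diurnal_profile = prof, bout_intensity_sdlog = 0,
                      seed = 5)
  sim <- generate_recording(cfg)
  ai <- compute_ai(sim$recording)
  expect_true(all(ai$per_minute$valid))
  expect_true(all(ai$per_minute$ai > 0 & ai$per_minute$ai < 0.01))
})

test_that("a fully masked minute is invalid", {
  rec <- random_recording(180, rate = 8, seed = 4)
  rec$valid_mask[(60 * 8 + 1):(120 * 8)] <- FALSE   # minute 2 gone
  ai <- compute_ai(rec)
  expect_identical(ai$per_minute$valid, c(TRUE, FALSE, TRUE))
  expect_true(all(ai$per_second$ai[!is.na(ai$per_second$ai)] >= 0))
})
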