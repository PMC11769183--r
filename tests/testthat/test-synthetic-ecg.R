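test_that("RR series honor mean, variance and seeding", {
  # zero-variance model is exactly the mean
  expect_equal(generate_rr_series(rr_model(0.8, 0), 5, seed = 1), rep(0.8, 5))
  # seeded determinism
  m <- rr_model(0.8, 0.05)
  expect_identical(generate_rr_series(m, 50, seed = 7),
                   generate_rr_series(m, 50, seed = 7))
  # moment recovery within 3 standard errors at n = 1000
  rr <- generate_rr_series(rr_model(0.8, 0.05), 1000, seed = 3)
  expect_lt(abs(mean(rr) - 0.8), 3 * 0.05 / sqrt(1000))
  expect_lt(abs(sd(rr) - 0.05), 3 * 0.05 / sqrt(2 * 999))
  # AR(1) keeps the marginal moments and adds positive lag-1 correlation
  rr_ar <- generate_rr_series(rr_model(0.8, 0.05, method = "ar1", ar = 0.6),
                              2000, seed = 5)
  # the AR(1) mean has standard error inflated by sqrt((1 + ar) / (1 - ar))
  expect_lt(abs(mean(rr_ar) - 0.8), 4 * 0.05 / sqrt(2000) * 2)
  expect_gt(cor(rr_ar[-1], rr_ar[-length(rr_ar)]), 0.4)
  # all intervals positive even under extreme variance
  expect_true(all(generate_rr_series(rr_model(0.4, 0.5), 500, seed = 2) > 0))
  expect_error(generate_rr_series(rr_model(0.8, 0.05), 0), class = "fatiguecg_error")
})

test_that("rendered waveforms place beats at cumulative RR times", {
  # duration arithmetic: rr summing to 10 s at 130 Hz -> 1300 samples
  expect_length(render_ecg(rep(1, 10), fs = 130), 1300)
  # single beat, R wave only: global max ~1 at the R center sample
  tpl <- beat_template(p = c(-0.2, 0, 0.04), q = c(-0.045, 0, 0.015),
                       s = c(0.045, 0, 0.015), t = c(0.3, 0, 0.06))
  x <- render_ecg(c(1, 1), template = tpl, fs = 130)   # beats at t = 1 s, 2 s
  expect_equal(max(x), 1, tolerance = 1e-6)
  expect_equal(which.max(x[1:200]), 131)               # t = 1 s is sample 131
  # peak-detection oracle recovers programmed intervals within +/- 1 sample
  rr <- generate_rr_series(rr_model(0.8, 0.05), 60, seed = 2)
  ecg <- render_ecg(rr, fs = 130)
  pk <- detect_rpeaks(ecg)
  prog <- round(diff(cumsum(rr)) * 130)
  expect_gte(length(pk), 58)
  expect_lte(max(abs(diff(pk)[1:(length(pk) - 1)] - prog[1:(length(pk) - 1)])), 1)
  expect_error(render_ecg(numeric(0)), class = "fatiguecg_error")
})

test_that("noise injection is seeded, length-preserving and moment-correct", {
  x <- sin(seq(0, 10, length.out = 1300))
  # all-zero spec is the identity
  zero <- noise_spec(white_sd = 0, wander_amp = 0, powerline_amp = 0)
  expect_identical(add_noise(x, zero, seed = 1), x)
  # seeded determinism
  expect_identical(add_noise(x, noise_spec(), seed = 4),
                   add_noise(x, noise_spec(), seed = 4))
  # white sigma = 0.1 on zero signal: sample SD within 5%
  w <- add_noise(numeric(10000), noise_spec(white_sd = 0.1, wander_amp = 0,
                                            powerline_amp = 0), seed = 9)
  expect_length(w, 10000)
  expect_lt(abs(sd(w) - 0.1) / 0.1, 0.05)
})

test_that("cohorts carry class-consistent VAS, plausible demographics, and are reproducible", {
  co <- generate_cohort(n_subjects = 4, duration_s = 20, seed = 1)
  expect_equal(nrow(co), 4)
  expect_setequal(unique(co$class), c("F", "N"))
  expect_true(all(co$vas[co$class == "F"] > 80))
  expect_true(all(co$vas[co$class == "N"] <= 80))
  expect_true(all(co$age >= 18 & co$age <= 27))
  expect_true(all(vapply(co$ecg, length, numeric(1)) == floor(20 * 130)))
  # VAS trajectories are monotone and end at the recorded score
  expect_true(all(vapply(co$vas_trajectory, function(v) all(diff(v) >= 0), logical(1))))
  expect_equal(vapply(co$vas_trajectory, function(v) v[length(v)], numeric(1)), co$vas)
  # byte-identical regeneration under the same seed
  expect_identical(co, generate_cohort(n_subjects = 4, duration_s = 20, seed = 1))
  expect_error(generate_cohort(n_subjects = 1), class = "fatiguecg_error")
})

test_that("gender ratio approaches the 2:1 default over many draws", {
  co <- generate_cohort(n_subjects = 60, duration_s = 1, seed = 3,
                        noise = noise_spec(white_sd = 0, wander_amp = 0,
                                           powerline_amp = 0))
  frac_male <- mean(co$gender == "male")
  expect_gt(frac_male, 0.5)
  expect_lt(frac_male, 0.85)
})

test_that("class-separated RR models are recovered by the peak oracle", {
  # F (mean RR 0.90 s) and N (0.80 s) differ by >= 0.1 s: the oracle's
  # per-record mean RR should separate classes perfectly in seeded cohorts
  ok <- vapply(1:5, function(s) {
    co <- generate_cohort(n_subjects = 20, duration_s = 30, seed = s)
    mrr <- vapply(co$clean, oracle_mean_rr, numeric(1))
    max(mrr[co$class == "N"]) < min(mrr[co$class == "F"])
  }, logical(1))
  expect_true(all(ok))
})
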