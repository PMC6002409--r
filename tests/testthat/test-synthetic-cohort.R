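test_that("cohort_config validates fields and names the offender", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(omission_rate = 1.5), "omission_rate")
  expect_error(cohort_config(waiter_fraction = -0.1), "waiter_fraction")
  expect_error(cohort_config(hr_mean = -5), "hr_mean")
  expect_error(cohort_config(n_participants = 2.5), "n_participants")
  expect_error(cohort_config(counting_windows = numeric(0)), "counting_windows")
  expect_error(cohort_config(rmssd_range = c(50, 20)), "rmssd_range")
})

test_that("sample_cohort handles the empty case and is deterministic", {
  expect_length(sample_cohort(cohort_config(n_participants = 0, seed = 1)), 0)
  c1 <- sample_cohort(cohort_config(n_participants = 8, seed = 99))
  c2 <- sample_cohort(cohort_config(n_participants = 8, seed = 99))
  expect_identical(cohort_manifest(c1), cohort_manifest(c2))
  c3 <- sample_cohort(cohort_config(n_participants = 8, seed = 100))
  expect_false(identical(cohort_manifest(c1), cohort_manifest(c3)))
})

test_that("cohort-level means match the configured population values", {
  cohort <- sample_cohort(clean_config(n = 1000, seed = 11))
  m <- cohort_manifest(cohort)
  expect_gt(mean(m$hr_rest), 57)
  expect_lt(mean(m$hr_rest), 59)
  # sample means within 2 standard errors of the configured means
  se <- function(sd_pop, n) sd_pop / sqrt(n)
  expect_lt(abs(mean(m$go_mu) - 370), 2 * se(40, 1000))
  expect_lt(abs(mean(m$stop_latency_systole) - 203), 2 * se(25, 1000))
  expect_lt(abs(mean(m$stop_latency_diastole) - 221), 2 * se(25, 1000))
})

test_that("phenotype flags are assigned at the configured fractions", {
  cohort <- sample_cohort(cohort_config(n_participants = 60, seed = 5))
  m <- cohort_manifest(cohort)
  expect_equal(sum(m$is_waiter), 8)
  expect_equal(sum(m$is_nonconverger), 6)
  expect_equal(sum(m$is_waiter & m$is_nonconverger), 0)
})

test_that("generated RR series hit the requested heart rate and RMSSD", {
  # zero-variability limit: all intervals exactly the mean IBI
  p0 <- list(hr_rest = 60, rmssd_true = 0)
  rr0 <- generate_rr_series(p0, duration = 30000, seed = 1)
  expect_true(all(abs(ibi(rr0) - 1000) < 1e-9))

  p <- list(hr_rest = 60, rmssd_true = 50)
  rr <- generate_rr_series(p, duration = 150000, seed = 42)
  expect_gt(rmssd(rr), 42.5)
  expect_lt(rmssd(rr), 57.5)
  expect_gte(max(as.numeric(rr)), 150000)

  expect_error(generate_rr_series(p, duration = 500), "too short")
  expect_identical(
    as.numeric(generate_rr_series(p, 60000, seed = 7)),
    as.numeric(generate_rr_series(p, 60000, seed = 7))
  )
})

test_that("realized RMSSD converges to the target on long recordings", {
  for (s in 1:3) {
    p <- list(hr_rest = 40 + 10 * s, rmssd_true = 15 * s)
    rr <- generate_rr_series(p, duration = 600000, seed = s)
    expect_lt(abs(rmssd(rr) / p$rmssd_true - 1), 0.10)
    expect_lt(abs(heart_rate_bpm(rr) / p$hr_rest - 1), 0.05)
  }
})

test_that("rendered ECG places R maxima at the true beat times", {
  rr <- rr_series(c(1000, 2000, 3000), duration = 4000)
  ecg <- render_ecg(rr, sampling_rate = 1000)
  for (r in c(1000, 2000, 3000)) {
    win <- which(ecg$times > r - 400 & ecg$times < r + 400)
    peak_t <- ecg$times[win][which.max(ecg$samples[win])]
    expect_lt(abs(peak_t - r), 1.01)
    # R deflection taller than the T deflection of the same beat
    t_win <- which(ecg$times > r + 200 & ecg$times < r + 400)
    expect_gt(max(ecg$samples[win]), max(ecg$samples[t_win]))
  }
  expect_error(render_ecg(rr, sampling_rate = 200), "250")

  empty <- render_ecg(rr_series(numeric(0), duration = 2000),
                      sampling_rate = 500)
  expect_true(all(empty$samples == 0))
})

test_that("heartbeat counting data follow the window and thinning contracts", {
  p <- make_profile()
  p$counting_ability <- 1
  # beat grid at 0, 1000, 2000, ... so any w-second window holds w beats
  rr <- rr_series(seq(0, 250000, by = 1000), duration = 250000)
  ct <- generate_interoception_data(p, rr, seed = 3, count_noise_sd = 0)
  expect_equal(nrow(ct), 6)
  expect_setequal(ct$window_s, c(25, 30, 35, 40, 45, 50))
  expect_equal(ct$actual, ct$window_s)    # 60 bpm grid
  expect_equal(ct$counted, ct$actual)     # perfect perceiver, noise off
  expect_true(all(ct$confidence >= 0 & ct$confidence <= 100))

  short <- rr_series(seq(0, 100000, by = 1000), duration = 100000)
  expect_error(generate_interoception_data(p, short), "shorter")

  ct2 <- generate_interoception_data(p, rr, seed = 3, count_noise_sd = 0)
  expect_identical(ct, ct2)
})
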