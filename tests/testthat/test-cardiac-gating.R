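test_that("threshold detection recovers true R-peaks and flags T-wave leakage", {
  rr <- rr_series(c(1000, 2000, 3000), duration = 4000)
  ecg <- render_ecg(rr, sampling_rate = 1000)

  det <- detect_r_peaks(ecg, threshold = 0.5) # between T (0.3) and R (1.0)
  expect_length(det, 3)
  expect_true(all(abs(as.numeric(det) - c(1000, 2000, 3000)) <= 1.01))

  # threshold below the T amplitude: spurious detections, warned
  expect_warning(low <- detect_r_peaks(ecg, threshold = 0.1), "below 300 ms")
  expect_gt(length(low), 3)

  flat <- list(samples = rep(0, 1000), times = seq_len(1000),
               sampling_rate = 1000, duration = 1000)
  expect_warning(none <- detect_r_peaks(flat, threshold = 0.5), "flat")
  expect_length(none, 0)

  expect_error(detect_r_peaks(ecg, threshold = -1), "threshold")
})

test_that("next-R prediction adds the median of the last three intervals", {
  expect_equal(predict_next_r(c(-1000, -10, 990, 2000)), 3000)
  expect_equal(predict_next_r(c(0, 990, 1990, 3000)), 3000 + 1000)
  # robust to one ectopic-like interval among the three
  expect_equal(predict_next_r(c(0, 900, 1900, 3800)), 3800 + 1000)
  expect_error(predict_next_r(c(0, 1000, 2000)), "insufficient")
})

test_that("events are scheduled at the stated cardiac-phase offsets", {
  ev <- schedule_trial_events(10000, "stop_systole", ssd = 200)
  expect_equal(ev$stop_onset, 10290)
  expect_equal(ev$go_onset, 10090)
  expect_equal(ev$stop_onset - ev$go_onset, 200)

  ev <- schedule_trial_events(10000, "go_diastole")
  expect_equal(ev$go_onset, 9990)
  expect_true(is.na(ev$stop_onset))

  ev <- schedule_trial_events(10000, "go_control_d", ssd = 150)
  expect_equal(ev$go_onset, 9840)
  expect_true(is.na(ev$stop_onset))

  expect_error(schedule_trial_events(10000, "stop_diastole"), "ssd")
})

test_that("past-scheduled onsets roll forward to the next predicted beat", {
  ev <- schedule_trial_events(10000, "stop_systole", ssd = 600,
                              scheduling_time = 10000, ibi = 1000)
  expect_equal(ev$n_rolls, 1)
  expect_equal(ev$predicted_r, 11000)
  expect_equal(ev$go_onset, 11290 - 600)
  expect_gte(ev$go_onset, 10000)
})

test_that("timing precision scores offsets against per-event targets", {
  r_grid <- seq(0, 20000, by = 1000)
  true_r <- rr_series(r_grid, duration = 20000)
  # 10 systole go events scheduled from perfect predictions
  ev <- do.call(rbind, lapply(1:10, function(k) {
    schedule_trial_events(r_grid[k + 1], "go_systole", trial_id = as.character(k))
  }))
  tp <- timing_precision(ev, true_r)
  expect_equal(tp$by_phase$frac_within, 1)
  expect_equal(tp$by_type$mean_offset, 290)
  expect_equal(tp$by_type$mean_deviation, 0)

  # displace one event by 300 ms: fraction drops to 0.9
  ev2 <- ev
  ev2$go_onset[5] <- ev2$go_onset[5] + 300
  tp2 <- timing_precision(ev2, true_r)
  expect_equal(tp2$by_phase$frac_within, 0.9)

  # histogram is a partition: counts sum to the number of events
  expect_equal(sum(tp2$histogram$count), nrow(ev2))

  empty <- timing_precision(ev[0, ], true_r)
  expect_equal(nrow(empty$by_phase), 0)
})

test_that("achieved-offset error equals the R-prediction error on systole trials", {
  set.seed(31)
  p <- list(hr_rest = 58, rmssd_true = 40)
  rr <- generate_rr_series(p, duration = 120000, seed = 31)
  r <- as.numeric(rr)
  for (k in seq(5, 80, by = 5)) {
    pred <- r[k - 1] + median(diff(r[(k - 4):(k - 1)]))
    pred_err <- pred - r[k]
    ev <- schedule_trial_events(pred, "go_systole")
    tp <- timing_precision(ev, rr)
    # nearest R is the beat the prediction targeted at this error scale
    expect_equal(tp$events$achieved_offset - 290, pred_err, tolerance = 1e-9)
  }
})

test_that("median-of-3 prediction error is bounded by the series' worst deviation", {
  p <- list(hr_rest = 58, rmssd_true = 40)
  rr <- generate_rr_series(p, duration = 300000, seed = 17)
  r <- as.numeric(rr)
  n <- length(r)
  errs <- devs <- numeric(n - 4)
  for (k in 5:n) {
    med3 <- median(diff(r[(k - 4):(k - 1)]))
    errs[k - 4] <- abs((r[k - 1] + med3) - r[k])
    devs[k - 4] <- abs((r[k] - r[k - 1]) - med3)
  }
  expect_equal(errs, devs) # identity, brute-forced over the series
  expect_true(all(errs <= max(devs)))
})
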