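# Shared fixtures, all built in code.

# A profile with (near-)deterministic race components: go_sigma = 0 and a
# vanishing exponential tail make the go finishing time equal go_mu;
# stop_latency_sd_within = 0 makes the stop process deterministic.
make_profile <- function(go_mu = 400, go_sigma = 0, go_tau = 1e-9,
                         stop_systole = 150, stop_diastole = 150,
                         sd_within = 0, hr_rest = 60, rmssd_true = 40,
                         omission_rate = 0, is_waiter = FALSE,
                         is_nonconverger = FALSE, id = "fix") {
  structure(list(
    id = id, hr_rest = hr_rest, rmssd_true = rmssd_true,
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    stop_latency_systole = stop_systole, stop_latency_diastole = stop_diastole,
    stop_latency_sd_within = sd_within, omission_rate = omission_rate,
    is_waiter = is_waiter, is_nonconverger = is_nonconverger,
    bpq_items = rep(3, 45), bis_total = 60, counting_ability = 0.8,
    confidence_coupling = 0.5,
    counting_windows = c(25, 30, 35, 40, 45, 50)
  ), class = "participant_profile")
}

# A clean (no pathological phenotypes) study-default configuration.
clean_config <- function(n = 46, seed = NULL, ...) {
  cohort_config(n_participants = n, seed = seed,
                waiter_fraction = 0, nonconverger_fraction = 0, ...)
}

# Run one session and reduce it to the per-participant analysis row.
session_row <- function(profile, seed = NULL) {
  participant_results(run_session(profile, seed = seed))
}

# Constructed 60-participant condition-summary fixture: 46 compliant
# participants with seeded sampling noise, 8 identical "waiters" (long go RTs
# and long SSDs), 6 identical "non-convergers" (tracker success far from 50%).
exclusion_fixture <- function(seed = 2024) {
  withr::with_seed(seed, {
    n_norm <- 46
    normals <- data.frame(
      id = sprintf("n%02d", seq_len(n_norm)),
      go_rt_systole = rnorm(n_norm, 470, 40),
      go_rt_diastole = rnorm(n_norm, 474, 40),
      mean_ssd_systole = rnorm(n_norm, 243, 40),
      mean_ssd_diastole = rnorm(n_norm, 227, 40),
      inhib_success_systole = rnorm(n_norm, 0.5, 0.05),
      inhib_success_diastole = rnorm(n_norm, 0.5, 0.05),
      stringsAsFactors = FALSE
    )
    waiters <- data.frame(
      id = sprintf("w%02d", 1:8),
      go_rt_systole = 700, go_rt_diastole = 700,
      mean_ssd_systole = 430, mean_ssd_diastole = 430,
      inhib_success_systole = 0.5, inhib_success_diastole = 0.5,
      stringsAsFactors = FALSE
    )
    nonconv <- data.frame(
      id = sprintf("x%02d", 1:6),
      go_rt_systole = 470, go_rt_diastole = 470,
      mean_ssd_systole = 80, mean_ssd_diastole = 80,
      inhib_success_systole = 0.15, inhib_success_diastole = 0.15,
      stringsAsFactors = FALSE
    )
    out <- rbind(normals, waiters, nonconv)
    out[sample.int(nrow(out)), ]
  })
}
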