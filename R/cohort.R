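#' Cohort configuration
#'
#' Generative settings for a synthetic cohort of cardiac stop-signal-task
#' participants. Defaults reproduce the study conditions the analysis chain is
#' calibrated to: resting heart rate 58 bpm with a between-participant SD of
#' 10.05 bpm, go reaction times averaging ~470 ms (ex-Gaussian), true stop
#' latencies of 203 ms when the stop cue lands at systole and 221 ms at
#' diastole, a 60-participant intake containing 8 "waiters" (who slow down to
#' await stop cues) and 6 "non-convergers" (whose staircase cannot settle at
#' 50%), six heartbeat-counting windows of 25-50 s, and 45 body-perception
#' questionnaire items.
#'
#' @param n_participants number of participants to generate (>= 0).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @param hr_mean,hr_sd_between resting heart rate mean and
#'   between-participant SD, beats/min.
#' @param rmssd_range low/high bounds (ms) of the per-participant true RMSSD,
#'   sampled uniformly (via a Gaussian copula, so it can correlate with other
#'   traits).
#' @param go_mu,go_sigma,go_tau population means (ms) of the ex-Gaussian go-RT
#'   parameters; `go_mu + go_tau` is the mean go RT.
#' @param go_mu_sd,go_sigma_sd,go_tau_sd between-participant SDs (ms).
#' @param stop_latency_systole_mean,stop_latency_diastole_mean population mean
#'   true stop-process latencies (ms) by cardiac phase of the stop cue.
#' @param stop_latency_sd_between between-participant SD of the latencies, ms.
#' @param stop_latency_sd_within within-trial Gaussian noise SD on the stop
#'   latency, ms.
#' @param omission_rate per-trial probability of an attentional lapse (no go
#'   response).
#' @param waiter_fraction,nonconverger_fraction fractions of the cohort
#'   assigned to the two pathological phenotypes (rounded to the nearest
#'   count).
#' @param bpq_item_count number of body-perception questionnaire items (45).
#' @param counting_windows heartbeat-counting window durations, seconds.
#' @param effect_structure named numeric vector of target latent correlations;
#'   see [default_effect_structure()].
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_participants = 10, seed = 1)
#' cohort <- sample_cohort(cfg)
#' @export
cohort_config <- function(n_participants = 60,
                          seed = NULL,
                          hr_mean = 58,
                          hr_sd_between = 10.05,
                          rmssd_range = c(20, 60),
                          go_mu = 370, go_sigma = 50, go_tau = 100,
                          go_mu_sd = 40, go_sigma_sd = 10, go_tau_sd = 25,
                          stop_latency_systole_mean = 203,
                          stop_latency_diastole_mean = 221,
                          stop_latency_sd_between = 25,
                          stop_latency_sd_within = 20,
                          omission_rate = 0.02,
                          waiter_fraction = 8 / 60,
                          nonconverger_fraction = 6 / 60,
                          bpq_item_count = 45,
                          counting_windows = c(25, 30, 35, 40, 45, 50),
                          effect_structure = default_effect_structure()) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    hr_mean = hr_mean, hr_sd_between = hr_sd_between,
    rmssd_range = rmssd_range,
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    go_mu_sd = go_mu_sd, go_sigma_sd = go_sigma_sd, go_tau_sd = go_tau_sd,
    stop_latency_systole_mean = stop_latency_systole_mean,
    stop_latency_diastole_mean = stop_latency_diastole_mean,
    stop_latency_sd_between = stop_latency_sd_between,
    stop_latency_sd_within = stop_latency_sd_within,
    omission_rate = omission_rate,
    waiter_fraction = waiter_fraction,
    nonconverger_fraction = nonconverger_fraction,
    bpq_item_count = bpq_item_count,
    counting_windows = counting_windows,
    effect_structure = effect_structure
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num1 <- function(field, lo = -Inf, hi = Inf) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
      stop_field(field, sprintf("must be a single number in [%s, %s]", lo, hi))
    }
  }
  if (!is.numeric(cfg$n_participants) || length(cfg$n_participants) != 1L ||
      cfg$n_participants < 0 || cfg$n_participants != round(cfg$n_participants)) {
    stop_field("n_participants", "must be a non-negative integer")
  }
  for (f in c("omission_rate", "waiter_fraction", "nonconverger_fraction")) {
    num1(f, 0, 1)
  }
  for (f in c("hr_mean", "hr_sd_between", "go_mu", "go_sigma", "go_tau",
              "stop_latency_systole_mean", "stop_latency_diastole_mean",
              "stop_latency_sd_between", "stop_latency_sd_within")) {
    num1(f, lo = 1e-9)
  }
  for (f in c("go_mu_sd", "go_sigma_sd", "go_tau_sd")) num1(f, lo = 0)
  if (!is.numeric(cfg$rmssd_range) || length(cfg$rmssd_range) != 2L ||
      any(cfg$rmssd_range <= 0) || diff(cfg$rmssd_range) < 0) {
    stop_field("rmssd_range", "must be positive (low, high) bounds in ms")
  }
  if (!is.numeric(cfg$counting_windows) || length(cfg$counting_windows) == 0L ||
      any(cfg$counting_windows <= 0)) {
    stop_field("counting_windows", "must be a non-empty vector of positive seconds")
  }
  if (!is.numeric(cfg$bpq_item_count) || cfg$bpq_item_count < 1) {
    stop_field("bpq_item_count", "must be a positive count")
  }
  es <- cfg$effect_structure
  if (length(es) && (!is.numeric(es) || is.null(names(es)) || any(abs(es) > 1))) {
    stop_field("effect_structure", "must be a named numeric vector of correlations in [-1, 1]")
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @export
default_effect_structure <- function() {
  c(
    hr_rmssd = -0.54,             # faster hearts are less variable
    rmssd_sensibility = 0.32,     # vagal tone tracks felt bodily sensitivity
    rmssd_stop_diastole = 0.31,   # higher HRV, slower stopping at diastole
    sensibility_stop_systole = 0.37,
    stop_systole_diastole = 0.60  # stopping ability is a trait
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n=%d, HR %g (SD %g) bpm, stop latencies %g/%g ms (sys/dia)\n",
    x$n_participants, x$hr_mean, x$hr_sd_between,
    x$stop_latency_systole_mean, x$stop_latency_diastole_mean
  ))
  cat(sprintf("  waiters %.0f%%, non-convergers %.0f%%, seed %s\n",
              100 * x$waiter_fraction, 100 * x$nonconverger_fraction,
              if (is.null(x$seed)) "<current stream>" else x$seed))
  invisible(x)
}

# latent trait order used by the Gaussian copula
.latents <- c("hr", "rmssd", "sensibility", "stop_sys", "stop_dia")

effect_sigma <- function(es) {
  m <- diag(5)
  dimnames(m) <- list(.latents, .latents)
  put <- function(a, b, key) {
    if (!is.na(es[key])) m[a, b] <<- m[b, a] <<- unname(es[key])
  }
  put("hr", "rmssd", "hr_rmssd")
  put("rmssd", "sensibility", "rmssd_sensibility")
  put("rmssd", "stop_dia", "rmssd_stop_diastole")
  put("sensibility", "stop_sys", "sensibility_stop_systole")
  put("stop_sys", "stop_dia", "stop_systole_diastole")
  nearest_pd(m)
}

#' Sample a synthetic cohort
#'
#' Draws `n_participants` generative truth profiles from a [cohort_config()].
#' Correlated traits (resting heart rate, true RMSSD, interoceptive
#' sensibility, phase-specific stop latencies) are drawn through a Gaussian
#' copula whose pairwise targets come from `config$effect_structure`; the
#' remaining parameters are independent. The first `round(n * fraction)`
#' randomly chosen participants carry the waiter / non-converger phenotypes.
#'
#' @param config a [cohort_config()].
#' @return A list of `participant_profile` objects (possibly empty), with the
#'   config attached as attribute `config`.
#' @examples
#' cohort <- sample_cohort(cohort_config(n_participants = 4, seed = 7))
#' cohort[[1]]
#' @export
sample_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) validate_cohort_config(config)
  local_seed(config$seed)
  n <- as.integer(config$n_participants)
  if (n == 0L) {
    return(structure(list(), config = config))
  }
  sigma <- effect_sigma(config$effect_structure)
  z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = sigma)
  if (n == 1L) z <- matrix(z, nrow = 1)
  colnames(z) <- .latents

  hr_rest <- clamp(config$hr_mean + config$hr_sd_between * z[, "hr"], 35, 150)
  rmssd_true <- config$rmssd_range[1] +
    diff(config$rmssd_range) * pnorm(z[, "rmssd"])
  sens_latent <- 2.5 + 0.5 * z[, "sensibility"]
  stop_sys <- clamp(config$stop_latency_systole_mean +
                      config$stop_latency_sd_between * z[, "stop_sys"], 80, Inf)
  stop_dia <- clamp(config$stop_latency_diastole_mean +
                      config$stop_latency_sd_between * z[, "stop_dia"], 80, Inf)

  go_mu <- clamp(rnorm(n, config$go_mu, config$go_mu_sd), 200, Inf)
  go_sigma <- clamp(rnorm(n, config$go_sigma, config$go_sigma_sd), 10, Inf)
  go_tau <- clamp(rnorm(n, config$go_tau, config$go_tau_sd), 20, Inf)
  bis_total <- clamp(round(rnorm(n, 62, 9)), 30, 120)
  counting_ability <- plogis(rnorm(n, 1.1, 0.8))
  confidence_coupling <- runif(n, -0.9, 0.9)

  n_wait <- round(n * config$waiter_fraction)
  n_non <- round(n * config$nonconverger_fraction)
  flagged <- sample.int(n, min(n, n_wait + n_non))
  waiters <- flagged[seq_len(min(n_wait, length(flagged)))]
  nonconv <- setdiff(flagged, waiters)

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    is_waiter <- i %in% waiters
    bpq_items <- clamp(round(sens_latent[i] +
                               rnorm(config$bpq_item_count, 0, 0.9)), 1, 5)
    profiles[[i]] <- structure(list(
      id = sprintf("p%03d", i),
      hr_rest = hr_rest[i],
      rmssd_true = rmssd_true[i],
      # waiters inflate their go process by 3 between-participant SDs
      go_mu = go_mu[i] + if (is_waiter) 3 * config$go_mu_sd else 0,
      go_sigma = go_sigma[i],
      go_tau = go_tau[i],
      stop_latency_systole = stop_sys[i],
      stop_latency_diastole = stop_dia[i],
      stop_latency_sd_within = config$stop_latency_sd_within,
      omission_rate = config$omission_rate,
      is_waiter = is_waiter,
      is_nonconverger = i %in% nonconv,
      bpq_items = bpq_items,
      bis_total = bis_total[i],
      counting_ability = counting_ability[i],
      confidence_coupling = confidence_coupling[i],
      counting_windows = config$counting_windows
    ), class = "participant_profile")
  }
  structure(profiles, config = config)
}

#' @export
print.participant_profile <- function(x, ...) {
  flags <- c(if (x$is_waiter) "waiter", if (x$is_nonconverger) "non-converger")
  cat(sprintf(
    "<participant_profile> %s: HR %.1f bpm, RMSSD %.1f ms, goRT ~%.0f ms, stop %0.f/%0.f ms%s\n",
    x$id, x$hr_rest, x$rmssd_true, x$go_mu + x$go_tau,
    x$stop_latency_systole, x$stop_latency_diastole,
    if (length(flags)) paste0(" [", paste(flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Cohort manifest
#'
#' Flattens a sampled cohort into one row per participant (questionnaire item
#' vectors summarised by their mean).
#'
#' @param cohort result of [sample_cohort()].
#' @return A data.frame with one row per participant.
#' @export
cohort_manifest <- function(cohort) {
  if (!length(cohort)) {
    return(data.frame(id = character(0)))
  }
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(
      id = p$id, hr_rest = p$hr_rest, rmssd_true = p$rmssd_true,
      go_mu = p$go_mu, go_sigma = p$go_sigma, go_tau = p$go_tau,
      stop_latency_systole = p$stop_latency_systole,
      stop_latency_diastole = p$stop_latency_diastole,
      is_waiter = p$is_waiter, is_nonconverger = p$is_nonconverger,
      bpq_mean = mean(p$bpq_items), bis_total = p$bis_total,
      counting_ability = p$counting_ability,
      confidence_coupling = p$confidence_coupling,
      stringsAsFactors = FALSE
    )
  }))
}

#' Generate heartbeat-counting task data
#'
#' Emulates the heartbeat tracking task: the participant silently counts
#' perceived heartbeats over each configured window while the true beat count
#' comes from the RR series. Windows are presented in a randomised order,
#' back-to-back with a short gap. The reported count is a binomial thinning of
#' the true count at the participant's `counting_ability` plus integer noise
#' (floored at 0); the post-trial confidence rating (0-100 visual analogue
#' scale) is constructed to correlate with the realised per-trial accuracy at
#' the participant's `confidence_coupling`.
#'
#' @param profile a `participant_profile`.
#' @param rr an [rr_series()] long enough to host all windows (plus 3-s
#'   inter-trial gaps).
#' @param seed optional integer seed.
#' @param count_noise_sd SD (beats) of the integer reporting noise.
#' @return data.frame with one row per window: `window_s`, `t_start_ms`,
#'   `t_end_ms`, `actual`, `counted`, `confidence`.
#' @examples
#' p <- sample_cohort(cohort_config(n_participants = 1, seed = 3))[[1]]
#' rr <- generate_rr_series(p, duration = 260000, seed = 3)
#' generate_interoception_data(p, rr, seed = 3)
#' @export
generate_interoception_data <- function(profile, rr, seed = NULL,
                                        count_noise_sd = 1.5) {
  local_seed(seed)
  windows <- profile$counting_windows
  gap_ms <- 3000
  needed <- sum(windows) * 1000 + gap_ms * (length(windows) - 1)
  span <- attr(rr, "duration")
  if (span < needed) {
    stop(sprintf(
      "RR series (%.0f ms) shorter than the total counting window time (%.0f ms)",
      span, needed
    ), call. = FALSE)
  }
  order <- sample.int(length(windows))
  windows <- windows[order]
  t0 <- cumsum(c(0, head(windows * 1000 + gap_ms, -1)))
  t1 <- t0 + windows * 1000
  r <- as.numeric(rr)
  actual <- vapply(seq_along(windows), function(i) {
    sum(r >= t0[i] & r < t1[i])
  }, integer(1))
  if (any(actual == 0)) {
    stop("a counting window contains no heartbeats; RR series too sparse",
         call. = FALSE)
  }
  noise <- if (count_noise_sd > 0) round(rnorm(length(windows), 0, count_noise_sd)) else 0
  counted <- pmax(0, rbinom(length(windows), actual, profile$counting_ability) + noise)
  acc <- 1 - abs(actual - counted) / actual
  rho <- profile$confidence_coupling
  z_noise <- rnorm(length(windows))
  z_acc <- if (sd(acc) > 0) (acc - mean(acc)) / sd(acc) else rep(0, length(acc))
  conf_z <- rho * z_acc + sqrt(max(0, 1 - rho^2)) * z_noise
  confidence <- clamp(55 + 15 * conf_z, 0, 100)
  data.frame(
    window_s = windows, t_start_ms = t0, t_end_ms = t1,
    actual = actual, counted = counted, confidence = confidence
  )
}
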