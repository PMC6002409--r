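#' Build the 360-trial schedule
#'
#' The session comprises 360 trials in four blocks of 90: 240 go trials (60
#' timed to systole, 60 to diastole, 60 control trials drawing their onset
#' from the systole SSD tracker and 60 from the diastole tracker) and 120 stop
#' trials (60 stop-systole, 60 stop-diastole), in a pseudo-random order.
#'
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @return data.frame with columns `index` (1..360), `block` (1..4) and
#'   `trial_type`.
#' @examples
#' sched <- build_schedule(seed = 1)
#' table(sched$trial_type)
#' @export
build_schedule <- function(seed = NULL) {
  local_seed(seed)
  types <- rep(TRIAL_TYPES, each = 60L)
  types <- sample(types)
  data.frame(
    index = seq_len(360L),
    block = rep(1:4, each = 90L),
    trial_type = types,
    stringsAsFactors = FALSE
  )
}

#' Adaptive stop-signal-delay staircase
#'
#' One-up/one-down tracker: the stop signal delay (SSD) increases by one step
#' after each successful stop (making the next stop harder) and decreases by
#' one step after each failed stop, converging on the 50% inhibition point.
#' The SSD starts at 200 ms, moves in 50-ms steps and is floored at 0 ms.
#'
#' @param condition `"systole"` or `"diastole"`.
#' @param ssd starting SSD, ms.
#' @param step step size, ms.
#' @return A `staircase_tracker` object.
#' @examples
#' tr <- staircase_tracker("systole")
#' tr <- update_staircase(tr, stop_success = FALSE) # 200 -> 150
#' tr$ssd
#' @export
staircase_tracker <- function(condition = c("systole", "diastole"),
                              ssd = 200, step = 50) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(ssd), ssd >= 0, is.numeric(step), step > 0)
  structure(list(
    condition = condition, ssd = ssd, step = step,
    history = list(trial_index = integer(0), ssd = numeric(0),
                   stop_success = logical(0))
  ), class = "staircase_tracker")
}

#' @rdname staircase_tracker
#' @param tracker a `staircase_tracker`.
#' @param stop_success logical: was the response successfully withheld?
#' @param trial_index optional trial index recorded in the history.
#' @export
update_staircase <- function(tracker, stop_success, trial_index = NA_integer_) {
  stopifnot(inherits(tracker, "staircase_tracker"), is.logical(stop_success))
  h <- tracker$history
  h$trial_index <- c(h$trial_index, trial_index)
  h$ssd <- c(h$ssd, tracker$ssd)
  h$stop_success <- c(h$stop_success, stop_success)
  tracker$history <- h
  tracker$ssd <- if (stop_success) {
    tracker$ssd + tracker$step
  } else {
    max(tracker$ssd - tracker$step, 0)
  }
  tracker
}

#' @rdname staircase_tracker
#' @return `tracker_history()` returns the per-stop-trial history (the SSD in
#'   force on each trial and its outcome) as a data.frame.
#' @export
tracker_history <- function(tracker) {
  as.data.frame(tracker$history)
}

#' @export
print.staircase_tracker <- function(x, ...) {
  cat(sprintf("<staircase_tracker> %s: SSD %g ms (step %g), %d stop trials\n",
              x$condition, x$ssd, x$step, nrow(x$history)))
  invisible(x)
}

# Draw one ex-Gaussian go finishing time; waiters inflate go_mu at sampling
# time, so no special-casing here.
draw_go_finish <- function(profile) {
  max(rnorm(1, profile$go_mu, profile$go_sigma) + rexp(1, 1 / profile$go_tau),
      100)
}

# Draw one stop-process latency for the given phase. Non-convergers draw from
# an asymmetric bimodal mixture (stop process engaged on only 15% of trials),
# which puts their 50% inhibition point below the SSD floor.
draw_stop_latency <- function(profile, phase) {
  base <- if (phase == "systole") {
    profile$stop_latency_systole
  } else {
    profile$stop_latency_diastole
  }
  sd_w <- profile$stop_latency_sd_within %||% 20
  if (isTRUE(profile$is_nonconverger) && runif(1) > 0.15) {
    return(max(rnorm(1, 1200, 100), 100))
  }
  max(rnorm(1, base, sd_w), 30)
}

#' Simulate one trial under the independent race model
#'
#' The go process finishes at an ex-Gaussian time; on stop trials the stop
#' process finishes at `ssd + stop latency(phase) + noise`, and the response
#' is produced if and only if the go process wins the race. Go finishing
#' times beyond the 1000-ms response window are omissions, as are attentional
#' lapses (probability `omission_rate`).
#'
#' @param profile a `participant_profile`.
#' @param trial_type one of the six trial classes.
#' @param ssd stop signal delay (ms); required for stop trials.
#' @param seed optional integer seed.
#' @return One-row data.frame: `trial_type`, `ssd_used`, `go_rt` (NA on
#'   omissions and successful stops), `responded`, `stop_success` (NA on go
#'   trials), `omission` (go trials only).
#' @examples
#' p <- sample_cohort(cohort_config(n_participants = 1, seed = 2))[[1]]
#' simulate_trial(p, "stop_systole", ssd = 200, seed = 5)
#' @export
simulate_trial <- function(profile, trial_type, ssd = NA_real_, seed = NULL) {
  trial_type <- match.arg(trial_type, TRIAL_TYPES)
  local_seed(seed)
  is_stop <- grepl("^stop", trial_type)
  if (is_stop && (is.na(ssd) || ssd < 0)) {
    stop_field("ssd", "stop trials need a non-negative SSD")
  }
  lapse <- runif(1) < (profile$omission_rate %||% 0)
  go_finish <- if (lapse) Inf else draw_go_finish(profile)
  if (is_stop) {
    phase <- trial_phase(trial_type)
    stop_finish <- ssd + draw_stop_latency(profile, phase)
    responded <- go_finish < stop_finish && go_finish <= 1000
    data.frame(
      trial_type = trial_type, ssd_used = ssd,
      go_rt = if (responded) go_finish else NA_real_,
      responded = responded, stop_success = !responded,
      omission = NA, stringsAsFactors = FALSE
    )
  } else {
    responded <- go_finish <= 1000
    data.frame(
      trial_type = trial_type, ssd_used = NA_real_,
      go_rt = if (responded) go_finish else NA_real_,
      responded = responded, stop_success = NA,
      omission = !responded, stringsAsFactors = FALSE
    )
  }
}

#' Run one full cardiac stop-signal session
#'
#' Simulates the complete 360-trial session for one participant: before each
#' trial the (simulated) ECG is monitored for three fresh inter-beat
#' intervals, the next R-peak is predicted from their median, and the trial's
#' events are scheduled at the intended cardiac phase (+290 ms systole, -10 ms
#' diastole). Stop and control trials draw the SSD from their condition's
#' staircase tracker at execution time; stop outcomes update the tracker.
#' Trials are separated by a 1000-ms inter-trial interval plus the 3-beat
#' monitoring period. Achieved offsets from the nearest true R-peak are filled
#' in post hoc.
#'
#' @param profile a `participant_profile`.
#' @param rr optional [rr_series()] (context `"task"`) to run against; if
#'   NULL, one long enough for the session is generated from the profile.
#' @param seed optional integer seed governing schedule order, RR generation
#'   (when `rr` is NULL) and all race-model draws.
#' @param iti_ms inter-trial interval, ms.
#' @param n_trials number of trials (360 for the full session).
#' @return List of class `session`: `records` (one row per trial, including
#'   onsets and achieved offsets), `events` (scheduling columns only),
#'   `trackers` (final systole/diastole staircases), `rr`, `profile_id`.
#' @examples
#' p <- sample_cohort(cohort_config(n_participants = 1, seed = 2))[[1]]
#' s <- run_session(p, seed = 11, n_trials = 30)
#' head(s$records)
#' @export
run_session <- function(profile, rr = NULL, seed = NULL, iti_ms = 1000,
                        n_trials = 360L) {
  local_seed(seed)
  schedule <- build_schedule(seed = NULL)
  if (n_trials < 360L) schedule <- schedule[seq_len(n_trials), ]

  ibi_exp <- 60000 / profile$hr_rest
  if (is.null(rr)) {
    dur <- n_trials * (6 * ibi_exp + iti_ms + 1600) + 10000
    rr <- generate_rr_series(profile, duration = dur, seed = NULL,
                             context = "task")
  }
  r <- as.numeric(rr)
  n_r <- length(r)
  n <- nrow(schedule)

  # precompute per-trial vectors (hot loop below stays scalar-arithmetic only)
  type_v <- schedule$trial_type
  is_stop_v <- grepl("^stop", type_v)
  is_ctrl_v <- grepl("^go_control", type_v)
  phase_v <- trial_phase(type_v)
  offset_v <- phase_offset(phase_v)
  lapse_v <- runif(n) < (profile$omission_rate %||% 0)
  go_finish_v <- pmax(rnorm(n, profile$go_mu, profile$go_sigma) +
                        rexp(n, 1 / profile$go_tau), 100)
  go_finish_v[lapse_v] <- Inf
  sd_w <- profile$stop_latency_sd_within %||% 20
  lat_v <- pmax(rnorm(n, ifelse(phase_v == "systole",
                                profile$stop_latency_systole,
                                profile$stop_latency_diastole), sd_w), 30)
  if (isTRUE(profile$is_nonconverger)) {
    disengaged <- runif(n) > 0.15
    lat_v[disengaged] <- pmax(rnorm(sum(disengaged), 1200, 100), 100)
  }

  ssd_used <- go_rt <- go_onset <- stop_onset <- predicted_r <- rep(NA_real_, n)
  responded <- stop_success <- omission <- rep(NA, n)
  ssd_cur <- c(systole = 200, diastole = 200)
  hist_idx <- list(systole = integer(0), diastole = integer(0))
  hist_ssd <- list(systole = numeric(0), diastole = numeric(0))
  hist_out <- list(systole = logical(0), diastole = logical(0))

  idx <- 1L
  t_now <- 0
  for (i in seq_len(n)) {
    # monitor 4 fresh R-peaks (3 intervals) at/after t_now
    while (idx <= n_r && r[idx] < t_now) idx <- idx + 1L
    if (idx + 3L > n_r) {
      stop("RR series exhausted before the session completed", call. = FALSE)
    }
    d1 <- r[idx + 1L] - r[idx]
    d2 <- r[idx + 2L] - r[idx + 1L]
    d3 <- r[idx + 3L] - r[idx + 2L]
    med_ibi <- d1 + d2 + d3 - min(d1, d2, d3) - max(d1, d2, d3)
    sched_time <- r[idx + 3L]
    pred <- sched_time + med_ibi

    phase <- phase_v[i]
    ssd_i <- if (is_stop_v[i] || is_ctrl_v[i]) ssd_cur[[phase]] else NA_real_

    go_shift <- offset_v[i] -
      (if (is_stop_v[i] || is_ctrl_v[i]) ssd_i else 0)
    # roll to the next predicted beat rather than schedule in the past
    while (pred + go_shift < sched_time) pred <- pred + med_ibi
    go_onset[i] <- pred + go_shift
    stop_onset[i] <- if (is_stop_v[i]) pred + offset_v[i] else NA_real_
    predicted_r[i] <- pred
    ssd_used[i] <- ssd_i

    if (is_stop_v[i]) {
      resp <- go_finish_v[i] < ssd_i + lat_v[i] && go_finish_v[i] <= 1000
      responded[i] <- resp
      stop_success[i] <- !resp
      if (resp) go_rt[i] <- go_finish_v[i]
      hist_idx[[phase]] <- c(hist_idx[[phase]], i)
      hist_ssd[[phase]] <- c(hist_ssd[[phase]], ssd_i)
      hist_out[[phase]] <- c(hist_out[[phase]], !resp)
      ssd_cur[[phase]] <- if (resp) max(ssd_i - 50, 0) else ssd_i + 50
    } else {
      resp <- go_finish_v[i] <= 1000
      responded[i] <- resp
      omission[i] <- !resp
      if (resp) go_rt[i] <- go_finish_v[i]
    }
    trial_end <- go_onset[i] + if (isTRUE(responded[i])) go_rt[i] else 1000
    t_now <- trial_end + iti_ms
  }

  trackers <- list(
    systole = staircase_tracker("systole"),
    diastole = staircase_tracker("diastole")
  )
  for (ph in c("systole", "diastole")) {
    trackers[[ph]]$ssd <- ssd_cur[[ph]]
    trackers[[ph]]$history <- list(trial_index = hist_idx[[ph]],
                                   ssd = hist_ssd[[ph]],
                                   stop_success = hist_out[[ph]])
  }

  records <- cbind(schedule, data.frame(
    ssd_used = ssd_used, go_rt = go_rt, responded = responded,
    stop_success = stop_success, omission = omission,
    predicted_r = predicted_r, go_onset = go_onset, stop_onset = stop_onset
  ))
  records$intended_offset <- phase_offset(trial_phase(records$trial_type))
  anchor <- ifelse(grepl("^stop", records$trial_type),
                   records$stop_onset, records$go_onset)
  records$achieved_offset <- nearest_r_offset(anchor, r)

  events <- records[, c("index", "trial_type", "intended_offset",
                        "predicted_r", "go_onset", "stop_onset", "ssd_used",
                        "achieved_offset")]
  names(events)[names(events) == "ssd_used"] <- "ssd"

  structure(list(records = records, events = events, trackers = trackers,
                 rr = rr, profile_id = profile$id %||% NA_character_),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  rec <- x$records
  st <- rec[grepl("^stop", rec$trial_type), ]
  cat(sprintf("<session> %s: %d trials, stop success %.2f, final SSD %g/%g ms (sys/dia)\n",
              x$profile_id, nrow(rec),
              if (nrow(st) > 0) mean(st$stop_success) else NA_real_,
              x$trackers$systole$ssd, x$trackers$diastole$ssd))
  invisible(x)
}
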