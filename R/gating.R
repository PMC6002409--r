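#' Threshold-based R-peak detection
#'
#' Detects R-waves as local maxima exceeding an amplitude threshold, with a
#' 250-ms refractory window so that, when the threshold sits between the T-
#' and R-wave amplitudes, each beat yields exactly one detection. A threshold
#' below the T-wave amplitude produces spurious detections at ~290 ms after
#' each R; these show up as inter-beat intervals below the physiological
#' minimum and trigger a warning.
#'
#' @param trace an [render_ecg()] trace (or any list with `samples`, `times`,
#'   `sampling_rate`).
#' @param threshold amplitude threshold, must be > 0.
#' @param refractory_ms minimum separation between detections, ms.
#' @return An [rr_series()] of detection times (ms); empty (with a warning)
#'   for a flat or empty trace.
#' @examples
#' rr <- rr_series(c(1000, 2000, 3000), duration = 4000)
#' ecg <- render_ecg(rr, sampling_rate = 500)
#' detect_r_peaks(ecg, threshold = 0.5)
#' @export
detect_r_peaks <- function(trace, threshold, refractory_ms = 250) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_field("threshold", "must be a single positive amplitude")
  }
  y <- trace$samples
  n <- length(y)
  if (n < 3L || max(y) <= min(y)) {
    warning("flat or empty trace: no R-peaks detected")
    return(rr_series(numeric(0), duration = trace$duration %||% 0,
                     context = "task"))
  }
  mid <- 2:(n - 1L)
  is_max <- y[mid] > y[mid - 1L] & y[mid] >= y[mid + 1L] & y[mid] >= threshold
  cand <- trace$times[mid][is_max]
  kept <- numeric(0)
  last <- -Inf
  for (t in cand) {
    if (t - last >= refractory_ms) {
      kept <- c(kept, t)
      last <- t
    }
  }
  if (length(kept) > 1L && any(diff(kept) < 300)) {
    warning(paste(
      "detected inter-beat intervals below 300 ms:",
      "threshold may sit below the T-wave amplitude"
    ))
  }
  rr_series(kept, duration = trace$duration %||% max(trace$times),
            context = "task")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the next R-wave peak
#'
#' The scheduler's beat predictor: the next R-peak is forecast as the last
#' observed R-peak time plus the median of the last three inter-beat
#' intervals. The median makes the prediction robust to a single ectopic-like
#' interval among the three.
#'
#' @param r_times numeric vector of observed R-peak times (ms); at least 4
#'   (three intervals) are required.
#' @return Predicted time (ms) of the next R-peak.
#' @examples
#' predict_next_r(c(0, 990, 1990, 3000)) # 3000 + median(990, 1000, 1010)
#' @export
predict_next_r <- function(r_times) {
  r_times <- as.numeric(r_times)
  if (length(r_times) < 4L) {
    stop("insufficient beats: need >= 3 inter-beat intervals (4 R-peaks)",
         call. = FALSE)
  }
  last3 <- diff(tail(r_times, 4L))
  tail(r_times, 1L) + median(last3)
}

TRIAL_TYPES <- c("go_systole", "go_diastole", "go_control_s", "go_control_d",
                 "stop_systole", "stop_diastole")

trial_phase <- function(trial_type) {
  ifelse(grepl("_s(ystole)?$", trial_type), "systole", "diastole")
}

phase_offset <- function(phase) ifelse(phase == "systole", 290, -10)

#' Schedule the events of one trial relative to a predicted R-peak
#'
#' Implements the cardiac-phase timing rules: systole-timed events land 290 ms
#' after the predicted R-peak and diastole-timed events 10 ms before it. On
#' stop trials the *stop* cue is phase-timed and the go cue precedes it by the
#' current stop signal delay (SSD); on phase-timed go trials the go cue itself
#' lands at the phase; on control go trials the go cue lands where it would on
#' the corresponding stop trial (phase offset minus the current tracker SSD),
#' with no stop cue. If the scheduled go onset would fall before the
#' scheduling time (large SSD, early beat), the whole event is rolled forward
#' to the next predicted beat rather than raising an error.
#'
#' @param prediction predicted R-peak time, ms.
#' @param trial_type one of `r paste0('"', TRIAL_TYPES, '"', collapse = ", ")`.
#' @param ssd current stop signal delay (ms); required (>= 0) for stop and
#'   control trials, ignored for phase-timed go trials.
#' @param scheduling_time time at which scheduling happens (ms); onsets are
#'   never scheduled before it.
#' @param ibi inter-beat interval (ms) used when rolling to the next beat.
#' @param trial_id optional label.
#' @return One-row data.frame: `trial_id`, `trial_type`, `intended_offset`,
#'   `predicted_r`, `go_onset`, `stop_onset` (NA for go trials), `ssd`,
#'   `n_rolls`.
#' @examples
#' schedule_trial_events(10000, "stop_systole", ssd = 200)
#' schedule_trial_events(10000, "go_diastole")
#' @export
schedule_trial_events <- function(prediction, trial_type, ssd = NA_real_,
                                  scheduling_time = -Inf, ibi = NULL,
                                  trial_id = NA_character_) {
  trial_type <- match.arg(trial_type, TRIAL_TYPES)
  is_stop <- grepl("^stop", trial_type)
  is_control <- grepl("^go_control", trial_type)
  if ((is_stop || is_control) && (is.na(ssd) || ssd < 0)) {
    stop_field("ssd", "stop and control trials need a non-negative SSD")
  }
  offset <- phase_offset(trial_phase(trial_type))
  n_rolls <- 0L
  repeat {
    if (is_stop) {
      stop_onset <- prediction + offset
      go_onset <- stop_onset - ssd
    } else if (is_control) {
      stop_onset <- NA_real_
      go_onset <- prediction + offset - ssd
    } else {
      stop_onset <- NA_real_
      go_onset <- prediction + offset
    }
    if (go_onset >= scheduling_time) break
    if (is.null(ibi)) {
      stop("scheduled go onset precedes scheduling time and no `ibi` was given to roll forward",
           call. = FALSE)
    }
    prediction <- prediction + ibi
    n_rolls <- n_rolls + 1L
  }
  data.frame(
    trial_id = trial_id, trial_type = trial_type, intended_offset = offset,
    predicted_r = prediction, go_onset = go_onset, stop_onset = stop_onset,
    ssd = if (is_stop || is_control) ssd else NA_real_, n_rolls = n_rolls,
    stringsAsFactors = FALSE
  )
}

# Signed offset of each event time from its nearest true R-peak.
nearest_r_offset <- function(t, r_times) {
  r <- as.numeric(r_times)
  idx <- findInterval(t, r)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(r))
  d_lo <- t - r[lo]
  d_hi <- t - r[hi]
  ifelse(idx == 0L, d_hi,
         ifelse(idx >= length(r), d_lo,
                ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)))
}

#' Timing precision of scheduled events within the cardiac cycle
#'
#' For each scheduled event, the *achieved offset* is the signed distance from
#' the phase-anchored event time (the stop onset on stop trials, the go onset
#' otherwise) to the nearest true R-peak. The *target offset* is where that
#' event was scheduled to land relative to the predicted R-peak (exactly +290
#' or -10 ms for phase-timed events; phase offset minus SSD for the go cues of
#' control trials). Precision is summarised per trial type and per intended
#' phase as the fraction of events whose achieved offset falls within 200 ms
#' of the target, plus a 50-ms-bin histogram of achieved offsets.
#'
#' @param events data.frame of scheduled events (as from
#'   [schedule_trial_events()] or [run_session()]).
#' @param true_r an [rr_series()] of ground-truth R-peak times.
#' @param bin_width histogram bin width, ms.
#' @param bin_range default histogram range (ms), extended if events fall
#'   outside it.
#' @param tolerance_ms the "within tolerance" criterion, ms.
#' @return List of class `timing_precision`: `events` (with `achieved_offset`,
#'   `target_offset`, `within_tol`), `by_type` and `by_phase` summaries, and
#'   `histogram` (per-type 50-ms bin counts).
#' @export
timing_precision <- function(events, true_r, bin_width = 50,
                             bin_range = c(-500, 800), tolerance_ms = 200) {
  empty <- structure(list(
    events = events,
    by_type = data.frame(), by_phase = data.frame(), histogram = data.frame(),
    tolerance_ms = tolerance_ms
  ), class = "timing_precision")
  if (is.null(events) || nrow(events) == 0L) return(empty)

  anchor <- ifelse(grepl("^stop", events$trial_type),
                   events$stop_onset, events$go_onset)
  if (length(true_r) == 0L) stop("`true_r` is empty", call. = FALSE)
  span <- range(as.numeric(true_r))
  if (any(anchor < span[1] - 2000 | anchor > span[2] + 2000)) {
    stop("events lie outside the span of `true_r`", call. = FALSE)
  }
  achieved <- nearest_r_offset(anchor, true_r)
  target <- anchor - events$predicted_r
  within <- abs(achieved - target) <= tolerance_ms
  ev <- events
  ev$achieved_offset <- achieved
  ev$target_offset <- target
  ev$within_tol <- within
  ev$phase <- trial_phase(ev$trial_type)

  summarise_group <- function(key) {
    groups <- split(seq_len(nrow(ev)), ev[[key]])
    do.call(rbind, lapply(names(groups), function(g) {
      i <- groups[[g]]
      data.frame(
        group = g, n = length(i),
        mean_offset = mean(achieved[i]), sd_offset = sd(achieved[i]),
        mean_deviation = mean(achieved[i] - target[i]),
        frac_within = mean(within[i]), stringsAsFactors = FALSE
      )
    }))
  }
  by_type <- summarise_group("trial_type")
  names(by_type)[1] <- "trial_type"
  by_phase <- summarise_group("phase")
  names(by_phase)[1] <- "phase"

  lo <- floor(min(bin_range[1], min(achieved)) / bin_width) * bin_width
  hi <- ceiling(max(bin_range[2], max(achieved)) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  hist_df <- do.call(rbind, lapply(split(achieved, ev$trial_type), function(a) {
    counts <- table(cut(a, breaks, right = FALSE, include.lowest = TRUE))
    data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
               count = as.integer(counts))
  }))
  hist_df$trial_type <- rep(names(split(achieved, ev$trial_type)),
                            each = length(breaks) - 1L)
  rownames(hist_df) <- NULL

  structure(list(events = ev, by_type = by_type, by_phase = by_phase,
                 histogram = hist_df, tolerance_ms = tolerance_ms),
            class = "timing_precision")
}

#' @export
print.timing_precision <- function(x, ...) {
  if (!nrow(x$by_phase)) {
    cat("<timing_precision> no events\n")
    return(invisible(x))
  }
  cat(sprintf("<timing_precision> %d events, tolerance %g ms\n",
              nrow(x$events), x$tolerance_ms))
  for (i in seq_len(nrow(x$by_phase))) {
    r <- x$by_phase[i, ]
    cat(sprintf("  %-8s mean %6.1f ms (SD %5.1f), %5.1f%% within tolerance\n",
                r$phase, r$mean_offset, r$sd_offset, 100 * r$frac_within))
  }
  invisible(x)
}
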