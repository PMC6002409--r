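#' Simulate a complete study
#'
#' Generates everything the analysis chain consumes, per participant: a
#' generative profile, a resting RR series (4 minutes: the first 2.5 minutes
#' are the heart-rate-variability window and the full span hosts the
#' heartbeat-counting windows), a full task session, and heartbeat-counting
#' data. Deterministic under `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param n_trials trials per session (360 for the full task).
#' @return List of class `study`: `participants` (each with `profile`,
#'   `rest_rr`, `session`, `counting`) and the `config`.
#' @examples
#' \donttest{
#' study <- simulate_study(cohort_config(n_participants = 3, seed = 1))
#' }
#' @export
simulate_study <- function(config, n_trials = 360L) {
  # one seeded stream for the whole study: cohort draws first, then each
  # participant's recordings/session/counting in order
  local_seed(config$seed)
  cfg_stream <- config
  cfg_stream$seed <- NULL
  cohort <- sample_cohort(cfg_stream)
  participants <- lapply(cohort, function(p) {
    rest_rr <- generate_rr_series(p, duration = 240000, context = "rest")
    session <- run_session(p, seed = NULL, n_trials = n_trials)
    counting <- generate_interoception_data(p, rest_rr)
    list(profile = p, rest_rr = rest_rr, session = session,
         counting = counting)
  })
  structure(list(participants = participants, config = config),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study> %d participants (seed %s)\n",
              length(x$participants),
              if (is.null(x$config$seed)) "<current stream>" else x$config$seed))
  invisible(x)
}

#' Derive one participant's analysis row
#'
#' Combines the behavioural condition summaries, the integration-method SSRT
#' per cardiac phase, the resting cardiac indices (RMSSD and bpm over the
#' first 2.5 minutes of rest), the three interoception dimensions, and the
#' trait impulsivity score into one row of the cohort results table.
#'
#' @param session a [run_session()] result.
#' @param rest_rr resting [rr_series()] (NULL leaves HRV fields `NA`).
#' @param counting heartbeat-counting data.frame (NULL leaves interoception
#'   fields `NA`).
#' @param profile the `participant_profile` (for questionnaire fields).
#' @param ssrt_go_pool `"pooled"` (all responded go trials feed the SSRT rank
#'   distribution; the default) or `"per_phase"` (only go trials whose onset
#'   came from that phase's timing/tracker).
#' @param rest_window_ms HRV analysis window, ms (2.5 minutes).
#' @return One-row data.frame.
#' @export
participant_results <- function(session, rest_rr = NULL, counting = NULL,
                                profile = NULL,
                                ssrt_go_pool = c("pooled", "per_phase"),
                                rest_window_ms = 150000) {
  ssrt_go_pool <- match.arg(ssrt_go_pool)
  cs <- condition_summaries(session$records, id = session$profile_id)
  ssrt_for <- function(phase) {
    p_resp <- cs[[paste0("p_respond_", phase)]]
    m_ssd <- cs[[paste0("mean_ssd_", phase)]]
    pool <- if (ssrt_go_pool == "pooled") cs$go_rt_pool else cs[[paste0("go_pool_", phase)]]
    if (is.na(p_resp) || is.na(m_ssd) || !length(pool) || p_resp == 0) {
      return(NA_real_)
    }
    # p_respond = 1 is computed (top rank) but flagged by ssrt_integration
    as.numeric(suppressWarnings(
      ssrt_integration(pool, omissions = cs$omissions, p_respond = p_resp,
                       mean_ssd = m_ssd)
    ))
  }
  hrv <- bpm <- NA_real_
  if (!is.null(rest_rr)) {
    hb <- rmssd_bpm(rest_rr, window_ms = rest_window_ms)
    hrv <- hb$rmssd
    bpm <- hb$bpm
  }
  accuracy <- awareness <- sensibility <- NA_real_
  if (!is.null(counting)) {
    sc <- suppressWarnings(interoception_scores(counting, profile$bpq_items))
    accuracy <- sc$accuracy
    awareness <- sc$awareness
    sensibility <- sc$sensibility
  }
  data.frame(
    id = cs$id,
    go_rt_systole = cs$go_rt_systole, go_rt_diastole = cs$go_rt_diastole,
    p_respond_systole = cs$p_respond_systole,
    p_respond_diastole = cs$p_respond_diastole,
    mean_ssd_systole = cs$mean_ssd_systole,
    mean_ssd_diastole = cs$mean_ssd_diastole,
    inhib_success_systole = cs$inhib_success_systole,
    inhib_success_diastole = cs$inhib_success_diastole,
    inhibition_success_overall = cs$inhibition_success_overall,
    omissions = cs$omissions,
    ssrt_systole = ssrt_for("systole"), ssrt_diastole = ssrt_for("diastole"),
    hrv_rmssd = hrv, bpm = bpm,
    bis_total = if (!is.null(profile)) profile$bis_total else NA_real_,
    accuracy = accuracy, awareness = awareness, sensibility = sensibility,
    stringsAsFactors = FALSE
  )
}

#' Analyse a simulated (or assembled) study
#'
#' Runs the full analysis chain: per-participant summaries and indices, the
#' two-pass 2-SD exclusion filter, the cardiac-phase contrasts, the
#' 10-variable correlation table with FDR adjustment, and the timing-precision
#' summary, assembled into report tables by [build_reports()].
#'
#' @param study a [simulate_study()] result (or a list with the same shape).
#' @param ssrt_go_pool passed to [participant_results()].
#' @return List of class `study_analysis`: `summaries` (all entrants),
#'   `exclusions`, `results` (retained participants), `timing` (pooled
#'   [timing_precision()]), `reports` (see [build_reports()]).
#' @export
analyse_study <- function(study, ssrt_go_pool = c("pooled", "per_phase")) {
  ssrt_go_pool <- match.arg(ssrt_go_pool)
  stopifnot(length(study$participants) > 0)
  summaries <- do.call(rbind, lapply(study$participants, function(pp) {
    participant_results(pp$session, pp$rest_rr, pp$counting, pp$profile,
                        ssrt_go_pool = ssrt_go_pool)
  }))
  exclusions <- apply_exclusions(summaries)
  results <- summaries[summaries$id %in% exclusions$retained, ]

  retained_timing <- lapply(study$participants, function(pp) {
    if (!(pp$session$profile_id %in% exclusions$retained)) return(NULL)
    tp <- timing_precision(pp$session$events, pp$session$rr)
    tp$events
  })
  pooled_events <- do.call(rbind, retained_timing)
  timing <- pooled_timing(pooled_events)

  reports <- build_reports(results, exclusions = exclusions, timing = timing)
  structure(list(summaries = summaries, exclusions = exclusions,
                 results = results, timing = timing, reports = reports),
            class = "study_analysis")
}

# Rebuild a timing_precision summary from pooled per-event rows that already
# carry achieved_offset / target_offset / within_tol.
pooled_timing <- function(ev, bin_width = 50, bin_range = c(-500, 800),
                          tolerance_ms = 200) {
  if (is.null(ev) || nrow(ev) == 0L) {
    return(structure(list(events = ev, by_type = data.frame(),
                          by_phase = data.frame(), histogram = data.frame(),
                          tolerance_ms = tolerance_ms),
                     class = "timing_precision"))
  }
  summarise_group <- function(key) {
    groups <- split(seq_len(nrow(ev)), ev[[key]])
    out <- do.call(rbind, lapply(names(groups), function(g) {
      i <- groups[[g]]
      data.frame(group = g, n = length(i),
                 mean_offset = mean(ev$achieved_offset[i]),
                 sd_offset = sd(ev$achieved_offset[i]),
                 mean_deviation = mean(ev$achieved_offset[i] -
                                         ev$target_offset[i]),
                 frac_within = mean(ev$within_tol[i]),
                 stringsAsFactors = FALSE)
    }))
    out
  }
  by_type <- summarise_group("trial_type")
  names(by_type)[1] <- "trial_type"
  by_phase <- summarise_group("phase")
  names(by_phase)[1] <- "phase"
  a <- ev$achieved_offset
  lo <- floor(min(bin_range[1], min(a)) / bin_width) * bin_width
  hi <- ceiling(max(bin_range[2], max(a)) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  groups <- split(a, ev$trial_type)
  hist_df <- do.call(rbind, lapply(names(groups), function(g) {
    counts <- table(cut(groups[[g]], breaks, right = FALSE,
                        include.lowest = TRUE))
    data.frame(trial_type = g, bin_lo = head(breaks, -1), bin_hi = breaks[-1],
               count = as.integer(counts), stringsAsFactors = FALSE)
  }))
  rownames(hist_df) <- NULL
  structure(list(events = ev, by_type = by_type, by_phase = by_phase,
                 histogram = hist_df, tolerance_ms = tolerance_ms),
            class = "timing_precision")
}

#' @export
print.study_analysis <- function(x, ...) {
  print(x$exclusions)
  if (nrow(x$results)) {
    cat(sprintf(
      "  retained cohort: SSRT %0.f/%0.f ms, SSD %0.f/%0.f ms, go RT %0.f/%0.f ms (sys/dia)\n",
      mean(x$results$ssrt_systole, na.rm = TRUE),
      mean(x$results$ssrt_diastole, na.rm = TRUE),
      mean(x$results$mean_ssd_systole, na.rm = TRUE),
      mean(x$results$mean_ssd_diastole, na.rm = TRUE),
      mean(x$results$go_rt_systole, na.rm = TRUE),
      mean(x$results$go_rt_diastole, na.rm = TRUE)
    ))
  }
  invisible(x)
}
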