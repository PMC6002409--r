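#' Per-participant condition summaries
#'
#' Summarises one session's trial records per cardiac phase: mean go RT over
#' responded phase-timed go trials, probability of responding on stop trials,
#' mean SSD in force across stop trials, per-tracker inhibition success, plus
#' the pooled go-RT distribution and omission count that feed the SSRT
#' estimator. A phase with no stop trials gets `NA` fields and a warning.
#'
#' @param records trial-record data.frame from [run_session()].
#' @param id optional participant id attached to the summary.
#' @return List of class `condition_summary` with scalar fields
#'   (`go_rt_systole`, `go_rt_diastole`, `p_respond_*`, `mean_ssd_*`,
#'   `inhib_success_*`, `inhibition_success_overall`, `omissions`) and vector
#'   fields `go_rt_pool` (all responded go-trial RTs) and per-phase go pools.
#' @export
condition_summaries <- function(records, id = NA_character_) {
  stopifnot(is.data.frame(records))
  is_stop <- grepl("^stop", records$trial_type)
  is_go <- !is_stop
  phase <- trial_phase(records$trial_type)

  out <- list(id = id)
  for (ph in c("systole", "diastole")) {
    suffix <- if (ph == "systole") "systole" else "diastole"
    timed_go <- is_go & records$trial_type == paste0("go_", ph)
    rts <- records$go_rt[timed_go & records$responded %in% TRUE]
    out[[paste0("go_rt_", suffix)]] <- if (length(rts)) mean(rts) else NA_real_

    st <- is_stop & phase == ph
    if (!any(st)) {
      warning(sprintf("no stop trials at %s: stop fields undefined", ph))
      out[[paste0("p_respond_", suffix)]] <- NA_real_
      out[[paste0("mean_ssd_", suffix)]] <- NA_real_
      out[[paste0("inhib_success_", suffix)]] <- NA_real_
    } else {
      out[[paste0("p_respond_", suffix)]] <- mean(records$responded[st])
      out[[paste0("mean_ssd_", suffix)]] <- mean(records$ssd_used[st])
      out[[paste0("inhib_success_", suffix)]] <- mean(records$stop_success[st])
    }
    # go pool restricted to this phase's timed + control go trials
    ph_pool <- is_go & phase == ph & records$responded %in% TRUE
    out[[paste0("go_pool_", suffix)]] <- records$go_rt[ph_pool]
  }
  out$inhibition_success_overall <-
    if (any(is_stop)) mean(records$stop_success[is_stop]) else NA_real_
  out$go_rt_pool <- records$go_rt[is_go & records$responded %in% TRUE]
  out$omissions <- sum(records$omission[is_go] %in% TRUE)
  structure(out, class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "<condition_summary> %s: goRT %0.f/%0.f ms, p(respond|stop) %.2f/%.2f, SSD %0.f/%0.f ms (sys/dia)\n",
    x$id, x$go_rt_systole, x$go_rt_diastole,
    x$p_respond_systole, x$p_respond_diastole,
    x$mean_ssd_systole, x$mean_ssd_diastole
  ))
  invisible(x)
}

#' Integration-method SSRT
#'
#' Estimates the stop signal reaction time: omissions are appended to the go
#' RT distribution as 1000-ms entries (the response-window maximum), the n go
#' RTs are rank-ordered, the RT at rank `ceiling(n * p_respond)` (1-based,
#' clamped to \[1, n\]) is read off, and the mean SSD is subtracted.
#'
#' `p_respond = 0` leaves the SSRT undefined (returns `NA` with a warning);
#' `p_respond = 1` is computed at rank `n` but flagged unreliable (warning and
#' attribute `unreliable`).
#'
#' @param go_rts numeric vector of responded go RTs (ms); at least one.
#' @param omissions number of go omissions to append at 1000 ms.
#' @param p_respond probability of responding on stop trials, in \[0, 1\].
#' @param mean_ssd mean stop signal delay, ms.
#' @return SSRT in ms (scalar), or `NA` when undefined.
#' @examples
#' ssrt_integration(c(400, 450, 500, 550, 600), 0, p_respond = 0.4,
#'                  mean_ssd = 200) # 450 - 200 = 250
#' @export
ssrt_integration <- function(go_rts, omissions = 0, p_respond, mean_ssd) {
  if (!length(go_rts)) stop("need at least one go RT", call. = FALSE)
  if (is.na(p_respond) || p_respond < 0 || p_respond > 1) {
    stop_field("p_respond", "must be a probability in [0, 1]")
  }
  if (p_respond == 0) {
    warning("p_respond = 0: SSRT undefined for this condition")
    return(NA_real_)
  }
  pool <- sort(c(go_rts, rep(1000, omissions)))
  n <- length(pool)
  k <- min(max(ceiling(n * p_respond), 1L), n)
  out <- pool[k] - mean_ssd
  if (p_respond >= 1) {
    warning("p_respond = 1: SSRT computed at the top rank, unreliable")
    attr(out, "unreliable") <- TRUE
  }
  out
}

#' Two-pass 2-SD cohort exclusion filter
#'
#' Pass 1 ("waiting"): participants whose mean go RT or mean SSD in either
#' cardiac condition exceeds the group mean by more than 2 standard deviations
#' (statistics over all entrants) are excluded for slowing down to await stop
#' cues. Pass 2 ("convergence"): among pass-1 survivors, participants whose
#' per-tracker inhibition success deviates from the survivors' mean by more
#' than 2 SD (either tracker, two-sided) are excluded because the staircase
#' failed to converge near 50%. Pass-2 statistics never include pass-1
#' exclusions.
#'
#' @param summaries data.frame with one row per participant and columns `id`,
#'   `go_rt_systole`, `go_rt_diastole`, `mean_ssd_systole`,
#'   `mean_ssd_diastole`, `inhib_success_systole`, `inhib_success_diastole`
#'   (as from [summarise_cohort()]).
#' @param n_sd the exclusion multiplier (2).
#' @return List of class `exclusion_result`: `retained` (ids), `excluded`
#'   (data.frame id/pass/reason), `flow` (entrants, after pass 1, retained).
#' @export
apply_exclusions <- function(summaries, n_sd = 2) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) < 3L) {
    stop("need at least 3 participants: 2-SD rules are undefined below that",
         call. = FALSE)
  }
  pass1_metrics <- c("go_rt_systole", "go_rt_diastole",
                     "mean_ssd_systole", "mean_ssd_diastole")
  pass2_metrics <- c("inhib_success_systole", "inhib_success_diastole")
  missing_cols <- setdiff(c("id", pass1_metrics, pass2_metrics),
                          names(summaries))
  if (length(missing_cols)) {
    stop_field(missing_cols[1], "column required by the exclusion filter")
  }

  # pass 1: one-sided (long RTs / long SSDs), stats over all entrants
  reasons1 <- vector("list", nrow(summaries))
  for (m in pass1_metrics) {
    x <- summaries[[m]]
    thr <- mean(x, na.rm = TRUE) + n_sd * sd(x, na.rm = TRUE)
    hit <- which(!is.na(x) & x > thr)
    for (i in hit) {
      reasons1[[i]] <- c(reasons1[[i]],
                         sprintf("%s = %.1f > %.1f (mean + %g SD)", m, x[i], thr, n_sd))
    }
  }
  out1 <- which(lengths(reasons1) > 0)
  survivors <- setdiff(seq_len(nrow(summaries)), out1)

  # pass 2: two-sided on per-tracker inhibition success, stats over survivors
  reasons2 <- vector("list", nrow(summaries))
  if (length(survivors) >= 3L) {
    for (m in pass2_metrics) {
      x <- summaries[[m]][survivors]
      mu <- mean(x, na.rm = TRUE)
      s <- sd(x, na.rm = TRUE)
      hit <- survivors[which(!is.na(x) & abs(x - mu) > n_sd * s)]
      for (i in hit) {
        reasons2[[i]] <- c(reasons2[[i]],
                           sprintf("%s = %.2f outside %.2f +/- %g*%.2f",
                                   m, summaries[[m]][i], mu, n_sd, s))
      }
    }
  }
  out2 <- which(lengths(reasons2) > 0)
  retained_idx <- setdiff(survivors, out2)

  excluded <- rbind(
    if (length(out1)) data.frame(
      id = summaries$id[out1], pass = 1L,
      reason = vapply(reasons1[out1], paste, "", collapse = "; "),
      stringsAsFactors = FALSE
    ),
    if (length(out2)) data.frame(
      id = summaries$id[out2], pass = 2L,
      reason = vapply(reasons2[out2], paste, "", collapse = "; "),
      stringsAsFactors = FALSE
    )
  )
  if (is.null(excluded)) {
    excluded <- data.frame(id = character(0), pass = integer(0),
                           reason = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    retained = summaries$id[retained_idx],
    excluded = excluded,
    flow = c(entrants = nrow(summaries),
             after_pass1 = length(survivors),
             retained = length(retained_idx))
  ), class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf("<exclusion_result> %d -> %d -> %d (entrants -> after waiting filter -> retained)\n",
              x$flow["entrants"], x$flow["after_pass1"], x$flow["retained"]))
  invisible(x)
}
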