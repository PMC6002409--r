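#' Resting cardiac indices: RMSSD and heart rate
#'
#' `rmssd()` is the root mean square of successive inter-beat-interval
#' differences (a time-domain, parasympathetically dominated heart rate
#' variability index); it needs at least 3 R-peaks (two intervals).
#' `heart_rate_bpm()` is `60000 / mean(IBI)` and needs at least 2 R-peaks.
#' `rmssd_bpm()` returns both.
#'
#' @param rr an [rr_series()] (or numeric vector of R-peak times, ms).
#' @param window_ms optional analysis window: only beats in
#'   `[0, window_ms]` are used (the resting analysis is fixed to the first
#'   2.5 minutes by the pipeline).
#' @return `rmssd()` and `heart_rate_bpm()` return scalars; `rmssd_bpm()` a
#'   list with `rmssd` (ms) and `bpm` (beats/min).
#' @examples
#' rr <- rr_series(cumsum(rep(1000, 11)))
#' rmssd_bpm(rr) # rmssd 0, bpm 60
#' @export
rmssd <- function(rr, window_ms = NULL) {
  r <- trim_window(rr, window_ms)
  if (length(r) < 3L) {
    stop("need at least 3 R-peaks (2 inter-beat intervals) for RMSSD",
         call. = FALSE)
  }
  sqrt(mean(diff(diff(r))^2))
}

#' @rdname rmssd
#' @export
heart_rate_bpm <- function(rr, window_ms = NULL) {
  r <- trim_window(rr, window_ms)
  if (length(r) < 2L) {
    stop("need at least 2 R-peaks for heart rate", call. = FALSE)
  }
  60000 / mean(diff(r))
}

#' @rdname rmssd
#' @export
rmssd_bpm <- function(rr, window_ms = NULL) {
  list(rmssd = rmssd(rr, window_ms), bpm = heart_rate_bpm(rr, window_ms))
}

trim_window <- function(rr, window_ms) {
  r <- as.numeric(rr)
  if (!is.null(window_ms)) r <- r[r <= window_ms]
  r
}

#' Three dimensions of interoception
#'
#' From heartbeat-counting trials and body-perception questionnaire items:
#' *accuracy* is the mean over trials of `1 - |actual - counted| / actual`
#' (not clipped: wild overcounting can push a trial score negative);
#' *awareness* is the Pearson correlation between per-trial accuracy and the
#' confidence rating (metacognitive correspondence), undefined (`NA`, with a
#' warning) when either has zero variance; *sensibility* is the mean of the
#' 45 questionnaire items.
#'
#' @param counting data.frame with columns `actual`, `counted`, `confidence`
#'   (one row per counting window); at least 2 rows for awareness.
#' @param bpq_items numeric vector of 45 ordinal item scores (1-5); NULL
#'   leaves sensibility `NA`.
#' @return List of class `interoception_scores`: `accuracy`, `awareness`,
#'   `sensibility`, `per_trial` (data.frame with per-trial accuracy).
#' @examples
#' ct <- data.frame(actual = c(30, 35, 40), counted = c(27, 30, 38),
#'                  confidence = c(60, 50, 75))
#' interoception_scores(ct, bpq_items = rep(3, 45))
#' @export
interoception_scores <- function(counting, bpq_items = NULL) {
  stopifnot(is.data.frame(counting),
            all(c("actual", "counted", "confidence") %in% names(counting)))
  if (any(counting$actual == 0)) {
    stop("a counting trial has zero actual beats: accuracy undefined",
         call. = FALSE)
  }
  acc <- 1 - abs(counting$actual - counting$counted) / counting$actual
  awareness <- NA_real_
  if (nrow(counting) >= 2L) {
    if (sd(acc) == 0 || sd(counting$confidence) == 0) {
      warning("zero variance in accuracy or confidence: awareness undefined")
    } else {
      awareness <- cor(acc, counting$confidence)
    }
  } else {
    warning("fewer than 2 counting trials: awareness undefined")
  }
  sensibility <- NA_real_
  if (!is.null(bpq_items)) {
    if (length(bpq_items) != 45L) {
      stop("sensibility requires the 45 body-perception questionnaire items",
           call. = FALSE)
    }
    sensibility <- mean(bpq_items)
  }
  structure(list(
    accuracy = mean(acc), awareness = awareness, sensibility = sensibility,
    per_trial = cbind(counting, accuracy = acc)
  ), class = "interoception_scores")
}

#' @export
print.interoception_scores <- function(x, ...) {
  cat(sprintf(
    "<interoception_scores> accuracy %.3f, awareness %s, sensibility %s\n",
    x$accuracy,
    if (is.na(x$awareness)) "NA" else sprintf("%.3f", x$awareness),
    if (is.na(x$sensibility)) "NA" else sprintf("%.2f", x$sensibility)
  ))
  invisible(x)
}
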