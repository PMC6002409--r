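#' RR-interval series
#'
#' An ordered series of R-peak event times for one participant, the substrate
#' for cardiac gating, RMSSD and heart-rate computation. Times are in
#' milliseconds from the start of the recording.
#'
#' Successive inter-beat intervals outside the physiological band
#' \[300, 2000\] ms are not an error (a detector run with a bad threshold can
#' produce them) but are flagged in the `ectopic_idx` attribute and noted by
#' `print()`.
#'
#' @param r_times numeric vector of strictly increasing R-peak times (ms).
#' @param duration recording duration in ms; defaults to the last event time.
#' @param context `"rest"` or `"task"`.
#' @return An object of class `rr_series`: the event-time vector with
#'   `duration`, `context` and `ectopic_idx` attributes.
#' @examples
#' rr <- rr_series(seq(0, 10000, by = 1000))
#' ibi(rr)
#' @export
rr_series <- function(r_times, duration = NULL, context = c("rest", "task")) {
  context <- match.arg(context)
  r_times <- as.numeric(r_times)
  if (any(!is.finite(r_times))) {
    stop_field("r_times", "all event times must be finite")
  }
  if (length(r_times) > 1L && any(diff(r_times) <= 0)) {
    stop_field("r_times", "event times must be strictly increasing")
  }
  if (is.null(duration)) {
    duration <- if (length(r_times)) max(r_times) else 0
  }
  d <- diff(r_times)
  structure(
    r_times,
    duration = as.numeric(duration),
    context = context,
    ectopic_idx = which(d < 300 | d > 2000),
    class = "rr_series"
  )
}

#' @rdname rr_series
#' @param rr an `rr_series`.
#' @export
ibi <- function(rr) diff(as.numeric(rr))

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf(
    "<rr_series> %d R-peaks over %.1f s (%s)\n",
    n, attr(x, "duration") / 1000, attr(x, "context")
  ))
  if (n > 2L) {
    cat(sprintf(
      "  mean IBI %.0f ms; %d interval(s) outside [300, 2000] ms\n",
      mean(ibi(x)), length(attr(x, "ectopic_idx"))
    ))
  }
  invisible(x)
}

#' Generate an RR-interval series with controllable RMSSD
#'
#' Inter-beat intervals follow a lag-1 autoregressive Gaussian process around
#' the profile's mean interval (`60000 / hr_rest`), with the innovation
#' variance chosen so that the expected root mean square of successive
#' differences equals `rmssd_true`. For an AR(1) process with coefficient
#' \eqn{\phi} and stationary variance \eqn{\sigma^2}, successive differences
#' have variance \eqn{2\sigma^2(1-\phi)}, so \eqn{\sigma =
#' \mathrm{RMSSD}/\sqrt{2(1-\phi)}}. Intervals are clamped to the
#' physiological band \[300, 2000\] ms.
#'
#' @param profile a `participant_profile`, or any list with `hr_rest`
#'   (beats/min) and `rmssd_true` (ms) fields.
#' @param duration requested recording length, ms; must cover at least two
#'   expected inter-beat intervals.
#' @param seed optional integer seed (NULL = current RNG stream).
#' @param context passed to [rr_series()].
#' @param phi AR(1) coefficient of the IBI process (0 <= phi < 1).
#' @return An [rr_series()] whose last event time is >= `duration`.
#' @examples
#' p <- list(hr_rest = 60, rmssd_true = 40)
#' rr <- generate_rr_series(p, duration = 150000, seed = 1)
#' rmssd(rr)
#' @export
generate_rr_series <- function(profile, duration, seed = NULL,
                               context = c("rest", "task"), phi = 0.8) {
  context <- match.arg(context)
  local_seed(seed)
  hr <- profile$hr_rest
  rmssd_true <- profile$rmssd_true
  if (!is.numeric(hr) || hr <= 0) stop_field("hr_rest", "must be > 0")
  if (!is.numeric(rmssd_true) || rmssd_true < 0) {
    stop_field("rmssd_true", "must be >= 0")
  }
  ibi_mean <- 60000 / hr
  if (duration < 2 * ibi_mean) {
    stop("`duration` too short: need at least 2 expected inter-beat intervals",
         call. = FALSE)
  }
  degenerate <- rmssd_true < 1e-9
  sd_stat <- if (degenerate) 0 else rmssd_true / sqrt(2 * (1 - phi))
  sd_innov <- sd_stat * sqrt(1 - phi^2)

  draw_chunk <- function(n, z0) {
    if (degenerate) return(rep(0, n))
    as.numeric(stats::filter(rnorm(n, 0, sd_innov), phi,
                             method = "recursive", init = z0))
  }

  n0 <- ceiling(duration / ibi_mean) + 30L
  z <- draw_chunk(n0, if (degenerate) 0 else rnorm(1, 0, sd_stat))
  ibis <- clamp(ibi_mean + z, 300, 2000)
  while (sum(ibis) < duration) {
    z_more <- draw_chunk(ceiling(n0 / 4) + 10L, z[length(z)])
    z <- c(z, z_more)
    ibis <- clamp(ibi_mean + z, 300, 2000)
  }
  r_times <- cumsum(ibis)
  keep <- seq_len(min(which(r_times >= duration)))
  rr_series(r_times[keep], duration = duration, context = context)
}

#' Synthetic ECG trace
#'
#' A minimal single-lead ECG built as a sum of Gaussian deflections: a tall,
#' narrow R-wave at each beat and a lower, wider T-wave centred 290 ms after
#' it (systole occurs around the T-wave peak). The trace is the substrate for
#' testing threshold-based R-peak detection, including its confusability with
#' T-waves; `true_r_times` carries the ground truth.
#'
#' @param rr an [rr_series()].
#' @param sampling_rate samples per second; must be >= 250 Hz for the +/- one
#'   sample peak-localization contract to hold.
#' @param r_amplitude,t_amplitude,r_width,t_width deflection heights
#'   (arbitrary units) and Gaussian SD widths (ms).
#' @param t_offset T-wave peak latency after the R-peak, ms.
#' @return An object of class `ecg_trace`: list with `sampling_rate`,
#'   `samples`, `times` (ms), `true_r_times` and `duration`.
#' @examples
#' rr <- rr_series(c(1000, 2000, 3000), duration = 4000)
#' ecg <- render_ecg(rr, sampling_rate = 500)
#' @export
render_ecg <- function(rr, sampling_rate = 1000,
                       r_amplitude = 1, t_amplitude = 0.3,
                       r_width = 8, t_width = 40, t_offset = 290) {
  if (sampling_rate < 250) {
    stop("`sampling_rate` must be >= 250 Hz for reliable peak localization",
         call. = FALSE)
  }
  stopifnot(r_amplitude > t_amplitude)
  duration <- attr(rr, "duration")
  step <- 1000 / sampling_rate
  times <- seq(0, duration, by = step)
  samples <- numeric(length(times))
  add_bump <- function(centre, amp, width) {
    lo <- max(1L, floor((centre - 5 * width) / step) + 1L)
    hi <- min(length(times), ceiling((centre + 5 * width) / step) + 1L)
    if (lo > hi) return(invisible(NULL))
    idx <- lo:hi
    samples[idx] <<- samples[idx] + amp * exp(-(times[idx] - centre)^2 / (2 * width^2))
    invisible(NULL)
  }
  for (r in as.numeric(rr)) {
    add_bump(r, r_amplitude, r_width)
    add_bump(r + t_offset, t_amplitude, t_width)
  }
  structure(
    list(sampling_rate = sampling_rate, samples = samples, times = times,
         true_r_times = as.numeric(rr), duration = duration),
    class = "ecg_trace"
  )
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.1f s at %g Hz, %d true R-peaks\n",
              x$duration / 1000, x$sampling_rate, length(x$true_r_times)))
  invisible(x)
}
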