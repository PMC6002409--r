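#' Read and write RR-interval series and trial tables
#'
#' Plain-text interchange formats: an RR series is a CSV with a single
#' `r_time_ms` column; a trial table carries one row per trial with the
#' columns written by [write_trials_csv()]. User-supplied per-trial tables in
#' this format can be fed straight into [condition_summaries()] /
#' [apply_exclusions()].
#'
#' @param rr an [rr_series()].
#' @param path file path.
#' @param context passed to [rr_series()] on read.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  write.csv(data.frame(r_time_ms = as.numeric(rr)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path, context = c("rest", "task")) {
  df <- read.csv(path)
  if (!"r_time_ms" %in% names(df)) {
    stop_field("r_time_ms", "column missing from RR series file")
  }
  rr_series(df$r_time_ms, context = match.arg(context))
}

#' @rdname write_rr_csv
#' @param records trial-record data.frame from [run_session()].
#' @export
write_trials_csv <- function(records, path) {
  cols <- c("index", "block", "trial_type", "ssd_used", "go_rt", "responded",
            "stop_success", "omission", "go_onset", "stop_onset",
            "achieved_offset")
  write.csv(records[, intersect(cols, names(records))], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_trials_csv <- function(path) {
  df <- read.csv(path)
  need <- c("trial_type", "responded")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_field(miss[1], "column missing from trial table")
  bad <- setdiff(unique(df$trial_type), TRIAL_TYPES)
  if (length(bad)) {
    stop_field("trial_type", sprintf("unknown trial type(s): %s",
                                     paste(bad, collapse = ", ")))
  }
  df
}

#' Write a simulated study to a directory
#'
#' One file per participant and stream: `rr_<id>.csv` (resting recording),
#' `trials_<id>.csv`, `events_<id>.csv`, `counting_<id>.csv`, plus a
#' cohort-level `profile_manifest.csv`.
#'
#' @param study a [simulate_study()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study_csv <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pp in study$participants) {
    id <- pp$profile$id
    write_rr_csv(pp$rest_rr, file.path(outdir, sprintf("rr_%s.csv", id)))
    write_trials_csv(pp$session$records,
                     file.path(outdir, sprintf("trials_%s.csv", id)))
    write.csv(pp$session$events,
              file.path(outdir, sprintf("events_%s.csv", id)),
              row.names = FALSE)
    write.csv(pp$counting, file.path(outdir, sprintf("counting_%s.csv", id)),
              row.names = FALSE)
  }
  manifest <- cohort_manifest(lapply(study$participants, `[[`, "profile"))
  write.csv(manifest, file.path(outdir, "profile_manifest.csv"),
            row.names = FALSE)
  invisible(outdir)
}
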