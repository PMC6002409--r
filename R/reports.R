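# Display labels for the 10-variable individual-differences correlation table.
TABLE1_VARS <- c(
  ssrt_systole = "SSRT-s", ssrt_diastole = "SSRT-d",
  mean_ssd_systole = "SSD-s", mean_ssd_diastole = "SSD-d",
  hrv_rmssd = "HRV", bpm = "bpm", bis_total = "Barratt",
  accuracy = "Interoceptive accuracy", awareness = "Interoceptive awareness",
  sensibility = "Interoceptive sensibility"
)

#' Assemble the report bundle
#'
#' Builds the analysis outputs in the shape of the published tables and
#' figures: (i) the 10-variable correlation table (45 pairs) with raw and
#' FDR-adjusted p values and significance markers; (ii) the condition means
#' with standard errors (go RT, SSRT, SSD at systole vs diastole) and their
#' paired contrasts; (iii) the timing-precision histogram in 50-ms bins per
#' trial type; (iv) the exclusion flow. Missing upstream fields yield missing
#' report cells, not a failed run.
#'
#' @param results per-participant results data.frame (retained cohort), as
#'   from [analyse_study()] / [participant_results()].
#' @param exclusions optional [apply_exclusions()] result.
#' @param timing optional [timing_precision()] result (pooled events).
#' @return List of class `report_bundle`: `table1`, `fig2_means`,
#'   `contrasts`, `fig1d_hist`, `exclusion_flow`.
#' @export
build_reports <- function(results, exclusions = NULL, timing = NULL) {
  stopifnot(is.data.frame(results))
  vars <- intersect(names(TABLE1_VARS), names(results))
  corr <- suppressWarnings(correlation_matrix_fdr(results, variables = vars))
  table1 <- corr$pairs
  table1$var1 <- unname(TABLE1_VARS[table1$var1])
  table1$var2 <- unname(TABLE1_VARS[table1$var2])
  table1$sig_uncorrected <- !is.na(table1$p) & table1$p < 0.05
  table1$sig_fdr <- !is.na(table1$p_fdr) & table1$p_fdr < 0.05

  measures <- list(
    go_rt = c("go_rt_systole", "go_rt_diastole"),
    ssrt = c("ssrt_systole", "ssrt_diastole"),
    ssd = c("mean_ssd_systole", "mean_ssd_diastole")
  )
  fig2 <- do.call(rbind, lapply(names(measures), function(m) {
    cols <- measures[[m]]
    do.call(rbind, lapply(seq_along(cols), function(j) {
      x <- results[[cols[j]]] %||% numeric(0)
      x <- x[!is.na(x)]
      data.frame(
        measure = m, phase = c("systole", "diastole")[j], n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        se = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  }))

  contrasts <- do.call(rbind, lapply(names(measures), function(m) {
    cols <- measures[[m]]
    x <- results[[cols[1]]] %||% rep(NA_real_, nrow(results))
    y <- results[[cols[2]]] %||% rep(NA_real_, nrow(results))
    ok <- complete.cases(x, y)
    if (sum(ok) < 3L || sd(x[ok] - y[ok]) == 0) {
      return(data.frame(measure = m, t = NA_real_, df = NA_real_,
                        p = NA_real_, mean_diff = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        eta_squared = NA_real_, stringsAsFactors = FALSE))
    }
    pt <- paired_t(x[ok], y[ok])
    data.frame(measure = m, t = pt$t, df = pt$df, p = pt$p,
               mean_diff = pt$mean_diff, ci_low = pt$ci95[1],
               ci_high = pt$ci95[2], eta_squared = pt$eta_squared,
               stringsAsFactors = FALSE)
  }))

  fig1d <- if (!is.null(timing)) timing$histogram else data.frame()

  flow <- if (!is.null(exclusions)) {
    list(
      entrants = unname(exclusions$flow["entrants"]),
      after_pass1 = unname(exclusions$flow["after_pass1"]),
      retained = unname(exclusions$flow["retained"]),
      flow = paste(exclusions$flow, collapse = " -> "),
      reasons = exclusions$excluded
    )
  } else {
    list(entrants = nrow(results), after_pass1 = nrow(results),
         retained = nrow(results),
         flow = paste(rep(nrow(results), 3), collapse = " -> "),
         reasons = data.frame())
  }

  structure(list(table1 = table1, fig2_means = fig2, contrasts = contrasts,
                 fig1d_hist = fig1d, exclusion_flow = flow),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> exclusion flow %s\n", x$exclusion_flow$flow))
  cat("condition contrasts (systole - diastole):\n")
  print(x$contrasts, digits = 3)
  cat(sprintf("correlation table: %d pairs, %d significant uncorrected, %d after FDR\n",
              nrow(x$table1), sum(x$table1$sig_uncorrected),
              sum(x$table1$sig_fdr)))
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits `table1.csv`, `fig2_means.csv`, `contrasts.csv`, `fig1d_hist.csv`,
#' `exclusion_flow.json` and a human-readable `report.md`.
#'
#' @param reports a [build_reports()] bundle.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(reports, outdir) {
  stopifnot(inherits(reports, "report_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(reports$table1, file.path(outdir, "table1.csv"), row.names = FALSE)
  write.csv(reports$fig2_means, file.path(outdir, "fig2_means.csv"),
            row.names = FALSE)
  write.csv(reports$contrasts, file.path(outdir, "contrasts.csv"),
            row.names = FALSE)
  write.csv(reports$fig1d_hist, file.path(outdir, "fig1d_hist.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    reports$exclusion_flow[c("entrants", "after_pass1", "retained", "flow")],
    file.path(outdir, "exclusion_flow.json"), auto_unbox = TRUE
  )
  md <- c(
    "# Cardiac stop signal task: analysis report", "",
    sprintf("Exclusion flow (entrants -> after waiting filter -> retained): %s",
            reports$exclusion_flow$flow), "",
    "## Condition contrasts (systole - diastole)", "",
    paste(utils::capture.output(print(reports$contrasts, digits = 3)),
          collapse = "\n"), "",
    "## Correlations",
    sprintf("%d pairs tested; %d significant uncorrected; %d survive FDR.",
            nrow(reports$table1), sum(reports$table1$sig_uncorrected),
            sum(reports$table1$sig_fdr))
  )
  writeLines(md, file.path(outdir, "report.md"))
  invisible(outdir)
}
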