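# Orchestration: the per-subject pipeline (preprocess -> phases ->
# hemodynamics -> metrics row) and the cohort-level statistical report.

#' Run the full per-subject analysis
#'
#' Chains the preprocessing corrections (temporal unwrap, polynomial
#' background correction over detected static tissue), mask time
#' resampling when frame counts differ, phase detection from the valve
#' probes, the Navier-Stokes force computation and the ratio metrics,
#' plus the optional inflow/outflow QC gate when valve discs are given.
#'
#' @param flow a [VelocityField4D-class].
#' @param mask the paired [Mask4D-class] (any frame count; resampled to
#'   the flow's).
#' @param lm a [Landmarks-class].
#' @param constants [fluidConstants()].
#' @param unwrap run [unwrapTemporal()] (default TRUE).
#' @param backgroundCorrect run [correctBackground()] (default TRUE).
#' @param static optional user-supplied [StaticTissueMask-class] for the
#'   background fit; when NULL it is detected from the (unwrapped) data.
#'   Supplying one is necessary when the background offset itself exceeds
#'   the static-speed threshold.
#' @param staticThreshold static-tissue speed threshold, m/s.
#' @param polyOrder background polynomial degree.
#' @param onsetFraction phase-detection onset fraction.
#' @param rmsDefinition see [ratioRms()].
#' @param mvPlane,aoPlane optional [flowDisc()]s enabling the QC gate.
#' @param id subject label for the results row.
#' @return one-row data.frame with the ratio metrics, phase timings, the
#'   E-wave-defined flag and (when QC ran) the QC fields; the projected
#'   [ForceSeries-class] and [CardiacPhases-class] are attached as
#'   attributes `force` and `phases`.
#' @export
runSubject <- function(flow, mask, lm, constants = fluidConstants(),
                       unwrap = TRUE, backgroundCorrect = TRUE,
                       static = NULL, staticThreshold = 0.02, polyOrder = 4L,
                       onsetFraction = 0.25,
                       rmsDefinition = "ratio_of_rms",
                       mvPlane = NULL, aoPlane = NULL, id = "subject") {
  stopifnot(is(flow, "VelocityField4D"), is(mask, "Mask4D"),
            is(lm, "Landmarks"))
  if (unwrap) flow <- unwrapTemporal(flow)
  if (backgroundCorrect) {
    if (is.null(static)) static <- detectStaticTissue(flow, staticThreshold)
    flow <- correctBackground(flow, static, polyOrder)
  }
  if (nFrames(mask) != nFrames(flow))
    mask <- resampleMaskTime(mask, nFrames(flow))

  mv <- probeSpeed(flow, lm@mvProbe)
  ao <- probeSpeed(flow, lm@aoProbe)
  phases <- segmentCycle(mv, ao, .dtS(flow), onsetFraction)

  qc <- NULL
  if (!is.null(mvPlane) && !is.null(aoPlane))
    qc <- flowDiscrepancy(flow, mvPlane, aoPlane, phases)

  metrics <- computeSubjectMetrics(flow, mask, lm, phases, constants,
                                   rmsDefinition)
  row <- data.frame(
    id = id,
    ratio_max_full = metrics$ratioMaxFull,
    ratio_max_E = metrics$ratioMaxE,
    ratio_max_A = metrics$ratioMaxA,
    ratio_rms_full = metrics$ratioRmsFull,
    ratio_rms_E = metrics$ratioRmsE,
    ratio_rms_A = metrics$ratioRmsA,
    t_max_sax_E = metrics$tMaxSax[["E"]],
    t_max_lax_E = metrics$tMaxLax[["E"]],
    t_max_sax_A = metrics$tMaxSax[["A"]],
    t_max_lax_A = metrics$tMaxLax[["A"]],
    e_defined = metrics$eDefined,
    systole_start = min(phases@systole), systole_end = max(phases@systole),
    stringsAsFactors = FALSE)
  if (!is.null(qc)) {
    row$qc_inflow_ml <- qc$inflow_ml
    row$qc_outflow_ml <- qc$outflow_ml
    row$qc_discrepancy <- qc$discrepancy
    row$qc_pass <- qc$pass
  }
  attr(row, "force") <- metrics$force
  attr(row, "phases") <- phases
  row
}

#' Cohort-level statistical report
#'
#' For each requested metric: per-group summaries (mean +/- SD when
#' compatible with normality, median (range) otherwise) and the
#' normality-gated two-group comparison. When covariates are available,
#' linear regressions of the E- and A-wave peak ratios on QRS duration
#' and on the septal-lateral mechanical delay.
#'
#' @param results per-subject results (rows from [runSubject()], with an
#'   `id` column).
#' @param covariates data.frame with `id`, `group` and optionally
#'   `qrs_ms`, `septal_lateral_delay_ms`.
#' @param metrics metric columns to compare.
#' @param alphaNormality normality-gate level for routing and summaries.
#' @return a `CohortReport` list: `table` (merged), `summaries`,
#'   `comparisons` (TestResult per metric), `regressions`.
#' @export
runCohort <- function(results, covariates,
                      metrics = c("ratio_max_full", "ratio_max_E",
                                  "ratio_max_A", "ratio_rms_full",
                                  "ratio_rms_E", "ratio_rms_A"),
                      alphaNormality = 0.05) {
  stopifnot(is.data.frame(results), is.data.frame(covariates))
  for (need in c("id", "group"))
    if (!need %in% names(covariates))
      stop("covariates must contain an '", need, "' column", call. = FALSE)
  tab <- merge(results, covariates, by = "id")
  if (length(unique(tab$group)) != 2L)
    stop("cohort error: exactly two groups are required", call. = FALSE)
  metrics <- intersect(metrics, names(tab))

  gl <- sort(unique(as.character(tab$group)))
  summaries <- lapply(stats::setNames(metrics, metrics), function(m) {
    vapply(gl, function(g)
      summarizeGroup(tab[[m]][tab$group == g], alphaNormality), character(1L))
  })
  comparisons <- lapply(stats::setNames(metrics, metrics), function(m)
    compareGroups(tab, m, alphaNormality))

  regressions <- list()
  for (cov in intersect(c("qrs_ms", "septal_lateral_delay_ms"), names(tab)))
    for (m in intersect(c("ratio_max_E", "ratio_max_A"), metrics)) {
      ok <- is.finite(tab[[cov]]) & is.finite(tab[[m]])
      if (sum(ok) >= 3L)
        regressions[[paste(m, "vs", cov)]] <-
          linearRegression(tab[[cov]][ok], tab[[m]][ok])
    }

  structure(list(table = tab, summaries = summaries,
                 comparisons = comparisons, regressions = regressions),
            class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("Cohort report:", nrow(x$table), "subjects,",
      paste(names(x$summaries[[1L]]), collapse = " vs "), "\n\n")
  for (m in names(x$comparisons)) {
    s <- x$summaries[[m]]
    r <- x$comparisons[[m]]
    cat(sprintf("  %-16s %s vs %s  p = %.4g (%s)\n", m, s[1L], s[2L],
                r$p, r$method))
  }
  if (length(x$regressions)) {
    cat("\n")
    for (nm in names(x$regressions)) {
      r <- x$regressions[[nm]]
      cat(sprintf("  %-32s r^2 = %.4f, p = %.4g (n = %d)\n", nm, r$r2,
                  r$p, r$n))
    }
  }
  invisible(x)
}
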