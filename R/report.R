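#' Run the full comparison pipeline on two dose files
#'
#' End-to-end convenience entry point: load both grids, convert to percent,
#' run the rotation pre-flight check, build the tolerance band, compute the
#' ISD curve, run the gamma baseline on the absolute grids, and bundle
#' everything in a [ComparisonReport-class]. The overall verdict is TRUE
#' when every usable level lies within +/-100% ISD and no rotation is
#' suspected; gamma is reported alongside but does not gate the verdict.
#'
#' @param ref,eval file paths (DICOM RTDOSE or plain container, see
#'   [loadDoseGrid()]) or [DoseGrid-class] objects.
#' @param levels evaluated isodose levels (%).
#' @param spatialTol spatial tolerance (mm).
#' @param normalization "global_max" or "explicit_dose" (see [toPercent()]).
#' @param normalizationDose dose (Gy) for "explicit_dose".
#' @param isoMrOverride optional user ISOmr.
#' @param seed RNG seed for the rotation probe draw.
#' @param rotationCheck run the rotation pre-flight (default TRUE).
#' @param gamma run the gamma baseline (default TRUE).
#' @param doseCriterion,dta,cutoff,gammaThreshold gamma settings.
#' @param isocenterOverride optional numeric(3), forwarded to
#'   [loadDoseGrid()] for file inputs.
#' @return a [ComparisonReport-class].
#' @export
runCompare <- function(ref, eval, levels = seq(10, 100, 5), spatialTol = 1.0,
                       normalization = c("global_max", "explicit_dose"),
                       normalizationDose = NULL, isoMrOverride = NULL,
                       seed = 1L, rotationCheck = TRUE, gamma = TRUE,
                       doseCriterion = 3, dta = 2, cutoff = 10,
                       gammaThreshold = 95, isocenterOverride = NULL) {
  normalization <- match.arg(normalization)
  label <- function(x) if (is.character(x)) x else class(x)[1]
  inputs <- list(reference = label(ref), evaluated = label(eval))
  if (is.character(ref)) ref <- loadDoseGrid(ref, isocenterOverride)
  if (is.character(eval)) eval <- loadDoseGrid(eval, isocenterOverride)

  pct <- function(g) {
    if (is(g, "PercentDoseGrid")) g
    else toPercent(g, normalization = normalization,
                   dose = normalizationDose)
  }
  ref_pct <- pct(ref)
  eval_pct <- pct(eval)

  curve <- compareDistributions(ref_pct, eval_pct, levels = levels,
                                spatialTol = spatialTol,
                                isoMrOverride = isoMrOverride,
                                rotationCheck = rotationCheck,
                                rotationSeed = seed)
  band <- buildToleranceBand(ref_pct, levels = levels,
                             spatialTol = spatialTol,
                             isoMrOverride = isoMrOverride)

  gamma_res <- NULL
  if (gamma && !is(ref, "PercentDoseGrid") && !is(eval, "PercentDoseGrid")) {
    gamma_res <- gammaIndex(ref, eval, doseCriterion = doseCriterion,
                            dta = dta, cutoff = cutoff,
                            threshold = gammaThreshold)
  }

  rot_bad <- !is.null(curve@rotation) && curve@rotation@rotationSuspected
  verdict <- all(curve@entries$withinTolerance) && !rot_bad
  config <- list(levels = levels, spatialTol = spatialTol,
                 normalization = normalization,
                 normalizationDose = normalizationDose,
                 isoMrOverride = isoMrOverride, seed = seed,
                 gamma = list(doseCriterion = doseCriterion, dta = dta,
                              cutoff = cutoff, threshold = gammaThreshold),
                 packageVersion = as.character(utils::packageVersion("isodiff")))
  new("ComparisonReport", inputs = inputs, config = config, curve = curve,
      band = band, gamma = gamma_res, verdict = verdict)
}

#' Write a comparison report to disk
#'
#' Emits a machine-readable JSON report (which fully reconstructs the ISD
#' chart: per-level table, tolerance band, rotation matrix, gamma summary,
#' configuration echo), a delimited per-level table, and the two charts.
#'
#' @param report a [ComparisonReport-class].
#' @param dir output directory (created if needed).
#' @param charts also write isd_chart.png / raw_tolerance_chart.png.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, dir, charts = TRUE) {
  stopifnot(is(report, "ComparisonReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curve <- report@curve
  rot <- curve@rotation
  payload <- list(
    inputs = report@inputs,
    config = report@config,
    isoMr = curve@isoMr,
    deltaUp = curve@deltaUp,
    deltaLow = curve@deltaLow,
    meanAbsIsd = curve@meanAbsIsd,
    entries = curve@entries,
    toleranceLimits = report@band@limits,
    rotation = if (is.null(rot)) NULL else list(
      levelsChecked = rot@levelsChecked,
      probePoints = rot@probePoints,
      bcMatrix = rot@bcMatrix,
      rotationSuspected = rot@rotationSuspected,
      epsilon = rot@epsilon,
      seed = rot@seed),
    gamma = if (is.null(report@gamma)) NULL else list(
      doseCriterion = report@gamma@doseCriterion,
      dta = report@gamma@dta,
      lowDoseCutoff = report@gamma@lowDoseCutoff,
      passingRate = report@gamma@passingRate,
      pass = report@gamma@pass),
    verdict = report@verdict)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(payload, paths[1], auto_unbox = TRUE, digits = NA,
                       null = "null")
  tab <- file.path(dir, "isd_table.tsv")
  utils::write.table(curve@entries, tab, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, tab)
  if (charts) {
    p1 <- file.path(dir, "isd_chart.png")
    p2 <- file.path(dir, "raw_tolerance_chart.png")
    ggplot2::ggsave(p1, plotIsd(curve), width = 7, height = 5, dpi = 120)
    ggplot2::ggsave(p2, plotRawTolerance(curve), width = 7, height = 5,
                    dpi = 120)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}

#' Rebuild an ISD chart from a written report
#'
#' Round-trip helper: reads \code{report.json} and reconstructs the
#' [IsdCurve-class] (and hence the chart) without re-running the pipeline.
#'
#' @param path path to a \code{report.json} written by [writeReport()].
#' @return an [IsdCurve-class].
#' @export
readReportCurve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("IsdCurve", entries = as.data.frame(x$entries), isoMr = x$isoMr,
      deltaUp = x$deltaUp, deltaLow = x$deltaLow,
      meanAbsIsd = x$meanAbsIsd, rotation = NULL)
}
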