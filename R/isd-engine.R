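#' Signed normalized isodose surface difference for one level
#'
#' Normalizes the raw Bray-Curtis dissimilarity BC_x against the tolerance
#' limit for this isodose and signs it by the median-distance comparison:
#' median_eval >= median_ref means the evaluated isodose sits farther from
#' the isocenter, i.e. the evaluated plan is hotter there (+), otherwise
#' cooler (-). The hotter branch is normalized by BC_ISOup and the cooler
#' branch by BC_ISOlow; \code{swapLimitPairing = TRUE} applies the
#' alternative geometric pairing (hotter vs BC_ISOlow) for sensitivity
#' analysis.
#'
#' @param bc Bray-Curtis value in [0, 1] for this level.
#' @param bcUp,bcLow the level's tolerance limits (both > 0).
#' @param medianEval,medianRef median distances of the raw samples (mm).
#' @param level isodose level (%), carried through.
#' @param swapLimitPairing swap which limit normalizes which branch.
#' @return one-row data.frame with columns level, bc, bcUp, bcLow,
#'   medianRef, medianEval, sign, isdPercent, limitUsed, withinTolerance.
#' @examples
#' computeIsdEntry(0.02, bcUp = 0.04, bcLow = 0.05,
#'                 medianEval = 49, medianRef = 50)$isdPercent  # -40
#' @export
computeIsdEntry <- function(bc, bcUp, bcLow, medianEval, medianRef,
                            level = NA_real_, swapLimitPairing = FALSE) {
  if (!is.finite(bcUp) || !is.finite(bcLow) || bcUp <= 0 || bcLow <= 0)
    stop("both tolerance limits must be positive at this level")
  if (bc < 0 || bc > 1) stop("'bc' must lie in [0, 1]")
  hotter <- medianEval >= medianRef
  use_up <- xor(!hotter, !swapLimitPairing)  # hotter -> up unless swapped
  limit <- if (use_up) bcUp else bcLow
  isd <- (if (hotter) 100 else -100) * bc / limit
  data.frame(level = level, bc = bc, bcUp = bcUp, bcLow = bcLow,
             medianRef = medianRef, medianEval = medianEval,
             sign = if (hotter) "+" else "-",
             isdPercent = isd,
             limitUsed = if (use_up) "BC_ISOup" else "BC_ISOlow",
             withinTolerance = abs(isd) <= 100,
             stringsAsFactors = FALSE)
}

#' Classify an isodose level into the PTV or Normal Tissue region
#'
#' Levels strictly above ISOmr conform to the target (PTV); ISOmr itself
#' and everything below belong to the Normal Tissue region.
#'
#' @param level isodose level(s) (%).
#' @param isoMr the reference isodose (%).
#' @return character vector, "PTV" or "NormalTissue".
#' @export
classifyRegion <- function(level, isoMr) {
  ifelse(level > isoMr, "PTV", "NormalTissue")
}

#' Compare two percent dose distributions isodose by isodose
#'
#' The full pipeline: build the tolerance band from the reference
#' distribution, extract each evaluated isodose surface from both grids,
#' parametrize them as distance histograms from their isocenters, score
#' each pair with Bray-Curtis, and normalize to signed ISD percentages.
#' Optionally runs the rotation pre-flight check first (isocentric
#' histograms are blind to rotations about the isocenter).
#'
#' @param ref,eval reference and evaluated [PercentDoseGrid-class] objects
#'   (a [DoseGrid-class] is converted with its own global maximum). The two
#'   frames must be registered so the stored isocenters refer to the same
#'   physical point.
#' @param levels evaluated isodose levels (%), default \code{seq(10, 100, 5)}.
#' @param spatialTol spatial tolerance criterion in mm (default 1).
#' @param isoMrOverride optional user-designated ISOmr.
#' @param normalize relative-frequency normalization for Bray-Curtis
#'   (default TRUE).
#' @param swapLimitPairing see [computeIsdEntry()].
#' @param rotationCheck run [runRotationCheck()] and attach its result.
#' @param rotationSeed RNG seed for the probe-point draw.
#' @param band optionally a precomputed [ToleranceBand-class].
#' @return an [IsdCurve-class]; entries for levels whose tolerance limit or
#'   surface is unavailable are dropped with a warning.
#' @export
compareDistributions <- function(ref, eval, levels = seq(10, 100, 5),
                                 spatialTol = 1.0, isoMrOverride = NULL,
                                 normalize = TRUE, swapLimitPairing = FALSE,
                                 rotationCheck = FALSE, rotationSeed = 1L,
                                 band = NULL) {
  ref <- .as_percent(ref)
  eval <- .as_percent(eval)
  if (is.null(band))
    band <- buildToleranceBand(ref, levels = levels, spatialTol = spatialTol,
                               isoMrOverride = isoMrOverride,
                               normalize = normalize)
  lim <- band@limits

  entries <- lapply(seq_len(nrow(lim)), function(i) {
    if (!lim$available[i]) return(NULL)
    x <- lim$level[i]
    d_ref <- tryCatch(
      distancesFromPoint(extractIsodoseSurface(ref, x, source = "reference"),
                         ref@isocenter),
      error = function(e) e)
    d_eval <- tryCatch(
      distancesFromPoint(extractIsodoseSurface(eval, x, source = "evaluated"),
                         eval@isocenter),
      error = function(e) e)
    if (inherits(d_ref, "error") || inherits(d_eval, "error")) {
      warning(sprintf("level %g%%: surface unavailable, dropped", x),
              call. = FALSE)
      return(NULL)
    }
    pair <- pairHistograms(d_ref, d_eval, level = x)
    bc <- brayCurtis(pair, normalize = normalize)
    computeIsdEntry(bc, bcUp = lim$bcUp[i], bcLow = lim$bcLow[i],
                    medianEval = stats::median(as.numeric(d_eval)),
                    medianRef = stats::median(as.numeric(d_ref)),
                    level = x, swapLimitPairing = swapLimitPairing)
  })
  entries <- do.call(rbind, entries[!vapply(entries, is.null, logical(1))])
  if (is.null(entries) || nrow(entries) < 2L)
    stop("fewer than 2 usable isodose levels; cannot assemble an ISD curve")
  entries <- entries[order(entries$level), , drop = FALSE]
  entries$region <- classifyRegion(entries$level, band@isoMr)
  rownames(entries) <- NULL

  rotation <- NULL
  if (rotationCheck) {
    rotation <- tryCatch(
      runRotationCheck(ref, eval, seed = rotationSeed,
                       normalize = normalize),
      error = function(e) {
        warning("rotation pre-flight check failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }

  new("IsdCurve", entries = entries, isoMr = band@isoMr,
      deltaUp = band@deltaUp, deltaLow = band@deltaLow,
      meanAbsIsd = mean(abs(entries$isdPercent)), rotation = rotation)
}

.as_percent <- function(grid) {
  if (is(grid, "PercentDoseGrid")) grid
  else if (is(grid, "DoseGrid")) toPercent(grid)
  else stop("expected a DoseGrid or PercentDoseGrid")
}
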