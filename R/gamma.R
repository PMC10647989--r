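#' Global gamma-index comparison of two dose grids
#'
#' Standard global-normalization gamma analysis used as the baseline
#' against which the isodose-shape comparison is reported: for every
#' reference voxel above the low-dose cutoff, the minimum over nearby
#' evaluated positions of sqrt((dose difference / criterion)^2 +
#' (distance / DTA)^2). Dose difference and cutoff are percentages of the
#' reference grid's maximum dose. The evaluated distribution is sampled by
#' trilinear interpolation on a displacement lattice of step
#' \code{dta * stepFraction} within a ball of radius
#' \code{dta * searchFactor}, with the displacement list sorted by distance
#' so the per-voxel search can stop as soon as the distance term alone
#' exceeds the best gamma found.
#'
#' @param ref,eval [DoseGrid-class] objects (Gy) on overlapping supports.
#' @param doseCriterion dose-difference criterion, % of the normalization
#'   dose (default 3).
#' @param dta distance-to-agreement criterion in mm (default 2).
#' @param cutoff low-dose cutoff, % of the normalization dose (default 10).
#' @param threshold passing-rate acceptance threshold, % (default 95).
#' @param searchFactor search radius in units of DTA (default 3).
#' @param stepFraction displacement lattice step in units of DTA
#'   (default 0.1).
#' @return a [GammaResult-class].
#' @examples
#' g <- makePlan(shape = "sphere", r0 = 15, gridDim = rep(33, 3))
#' passingRate(gammaIndex(g, g))  # 100
#' @export
gammaIndex <- function(ref, eval, doseCriterion = 3, dta = 2, cutoff = 10,
                       threshold = 95, searchFactor = 3, stepFraction = 0.1) {
  stopifnot(is(ref, "DoseGrid"), is(eval, "DoseGrid"))
  if (dta <= 0 || doseCriterion <= 0)
    stop("'dta' and 'doseCriterion' must be positive")
  dmax <- max(ref@values)
  if (dmax <= 0) stop("zero normalization dose: reference grid is empty")
  if (!.grids_overlap(ref, eval))
    stop("reference and evaluated grids have disjoint spatial supports")

  step <- dta * stepFraction
  radius <- dta * searchFactor
  g <- seq(-radius, radius, by = step)
  offsets <- as.matrix(expand.grid(x = g, y = g, z = g))
  nrm <- sqrt(rowSums(offsets^2))
  keep <- nrm <= radius + 1e-9
  offsets <- offsets[keep, , drop = FALSE]
  nrm <- nrm[keep]
  ord <- order(nrm)
  offsets <- offsets[ord, , drop = FALSE]
  nrm <- nrm[ord]

  gm <- .gamma_engine(
    as.vector(ref@values), dim(ref@values), ref@spacing, ref@origin,
    as.vector(eval@values), dim(eval@values), eval@spacing, eval@origin,
    offsets, nrm,
    dose_tol = doseCriterion / 100 * dmax, dta = dta,
    cutoff_dose = cutoff / 100 * dmax)
  gm <- array(gm, dim = dim(ref@values))
  evaluated <- sum(!is.na(gm))
  if (evaluated == 0L)
    stop("no voxels above the low-dose cutoff to evaluate")
  rate <- 100 * sum(gm <= 1, na.rm = TRUE) / evaluated
  new("GammaResult", doseCriterion = doseCriterion, dta = dta,
      lowDoseCutoff = cutoff, normalizationDose = dmax, gammaMap = gm,
      passingRate = rate, acceptanceThreshold = threshold,
      pass = rate >= threshold)
}

.grids_overlap <- function(a, b) {
  lo_a <- a@origin
  hi_a <- a@origin + (dim(a@values) - 1) * a@spacing
  lo_b <- b@origin
  hi_b <- b@origin + (dim(b@values) - 1) * b@spacing
  all(lo_a <= hi_b) && all(lo_b <= hi_a)
}
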