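#' Select the reference isodose ISOmr from the radius-difference curve
#'
#' Computes the midrange (max + min) / 2 of the successive-isodose
#' equivalent-radius differences and returns the level whose radius
#' difference is closest to it; ties break toward the higher level. In a
#' well-formed plan this lands on the shoulder of the dose falloff, the
#' isodose that separates target coverage from normal tissue.
#'
#' @param curve a [RadiusCurve-class].
#' @param override optional user-designated ISOmr level (returned as-is
#'   after a range check); useful for multi-target plans whose
#'   radius-difference curve crosses the midrange several times.
#' @return the ISOmr level (%).
#' @export
selectIsoMr <- function(curve, override = NULL) {
  stopifnot(is(curve, "RadiusCurve"))
  if (!is.null(override)) {
    if (!override %in% curve@levels)
      stop("'override' must be one of the curve levels")
    return(as.numeric(override))
  }
  ok <- is.finite(curve@radiusDiffs)
  if (sum(ok) < 2L) stop("radius curve has fewer than 2 usable levels")
  d <- curve@radiusDiffs[ok]
  lv <- curve@levels[ok]
  if (max(d) - min(d) <= 1e-12)
    stop("no gradient structure: radius-difference curve is flat")
  m <- (max(d) + min(d)) / 2
  dev <- abs(d - m)
  best <- which(dev <= min(dev) + 1e-12)
  max(lv[best])  # tie -> higher level
}

#' Map the spatial tolerance at ISOmr to a fixed dose interval
#'
#' On the piecewise-linear interpolation of the equivalent radius r(x) over
#' integer levels, finds ISOup (the level whose radius is spatialTol mm
#' smaller than r(ISOmr) -- closer to the isocenter) and ISOlow (radius
#' spatialTol mm larger). The returned offsets deltaUp = ISOup - ISOmr and
#' deltaLow = ISOmr - ISOlow define the plan's universal tolerance dose
#' interval, applied at every evaluated isodose.
#'
#' @param curve a [RadiusCurve-class] (radii non-increasing).
#' @param isoMr reference isodose level (%).
#' @param spatialTol spatial criterion in mm (default 1, the MLC QA
#'   tolerance).
#' @return list with \code{deltaUp}, \code{deltaLow} (percentage points)
#'   and the fractional \code{isoUp}, \code{isoLow} levels.
#' @export
deriveDoseInterval <- function(curve, isoMr, spatialTol = 1.0) {
  stopifnot(is(curve, "RadiusCurve"))
  if (spatialTol < 0) stop("'spatialTol' must be non-negative")
  lv <- curve@levels
  r <- curve@radii
  if (!isoMr %in% lv) stop("'isoMr' must be one of the curve levels")
  r_mr <- r[lv == isoMr]
  if (spatialTol == 0)
    return(list(deltaUp = 0, deltaLow = 0, isoUp = isoMr, isoLow = isoMr))

  iso_up <- .invert_radius(lv, r, r_mr - spatialTol, from = isoMr,
                           direction = "up")
  if (is.na(iso_up))
    stop("radius range too small to move ", spatialTol,
         " mm toward higher isodoses (closer to the isocenter)")
  iso_low <- .invert_radius(lv, r, r_mr + spatialTol, from = isoMr,
                            direction = "down")
  if (is.na(iso_low))
    stop("radius range too small to move ", spatialTol,
         " mm toward lower isodoses (away from the isocenter)")
  list(deltaUp = iso_up - isoMr, deltaLow = isoMr - iso_low,
       isoUp = iso_up, isoLow = iso_low)
}

## Find the level where the (non-increasing, piecewise linear) radius curve
## reaches `target`, scanning up or down from `from`. NA when unreachable.
.invert_radius <- function(lv, r, target, from, direction) {
  i0 <- which(lv == from)
  if (direction == "up") {
    idx <- which(r <= target & lv >= from)
    if (!length(idx)) return(NA_real_)
    j <- min(idx)
    if (j == i0) return(lv[i0])
    ## crossing between j-1 and j
    r1 <- r[j - 1L]; r2 <- r[j]
    if (r1 == r2) return(lv[j])
    lv[j - 1L] + (r1 - target) / (r1 - r2) * (lv[j] - lv[j - 1L])
  } else {
    idx <- which(r >= target & lv <= from)
    if (!length(idx)) return(NA_real_)
    j <- max(idx)
    if (j == i0) return(lv[i0])
    r1 <- r[j]; r2 <- r[j + 1L]
    if (r1 == r2) return(lv[j])
    lv[j] + (r1 - target) / (r1 - r2) * (lv[j + 1L] - lv[j])
  }
}

#' Build the plan-specific tolerance band from the reference distribution
#'
#' Derives ISOmr and the tolerance dose interval from the reference
#' radius curve, then for each evaluated level x compares his_x(ref) with
#' his_{x + deltaUp}(ref) and his_{x - deltaLow}(ref) (reference-anchored
#' shared bin edges) to obtain the Bray-Curtis acceptance limits BC_ISOup
#' and BC_ISOlow. Limits come from the reference distribution only.
#' Fractional offset levels are rounded to the nearest whole-percent
#' isodose for extraction; levels whose offset collapses onto x itself,
#' leaves the 1..100 range, or hits a missing isodose are flagged
#' unavailable (with a warning) rather than given a fabricated limit.
#'
#' @param refGrid reference [PercentDoseGrid-class].
#' @param levels evaluated isodose levels (%), default \code{seq(10, 100, 5)}.
#' @param spatialTol spatial criterion in mm (default 1).
#' @param isoMrOverride optional user ISOmr (see [selectIsoMr()]).
#' @param normalize normalize histograms to relative frequencies before the
#'   Bray-Curtis comparison (default TRUE).
#' @param curve optionally a precomputed [RadiusCurve-class] of refGrid.
#' @return a [ToleranceBand-class].
#' @export
buildToleranceBand <- function(refGrid, levels = seq(10, 100, 5),
                               spatialTol = 1.0, isoMrOverride = NULL,
                               normalize = TRUE, curve = NULL) {
  stopifnot(is(refGrid, "PercentDoseGrid"))
  if (is.null(curve)) curve <- buildRadiusCurve(refGrid)
  iso_mr <- selectIsoMr(curve, override = isoMrOverride)
  iv <- deriveDoseInterval(curve, iso_mr, spatialTol = spatialTol)
  if (iv$deltaUp <= 0 || iv$deltaLow <= 0)
    stop("degenerate tolerance interval: spatial tolerance maps to a zero ",
         "dose offset")

  cache <- new.env(parent = emptyenv())
  dist_at <- function(level) {
    key <- format(level)
    if (!exists(key, cache)) {
      val <- tryCatch(
        distancesFromPoint(
          extractIsodoseSurface(refGrid, level, source = "reference"),
          refGrid@isocenter),
        error = function(e) e)
      assign(key, val, cache)
    }
    get(key, cache)
  }

  rows <- lapply(levels, function(x) {
    lv_up <- round(x + iv$deltaUp)
    lv_low <- round(x - iv$deltaLow)
    reason <- NULL
    if (lv_up > 100 || lv_up <= x) reason <- "upper offset out of range"
    else if (lv_low < 1 || lv_low >= x) reason <- "lower offset out of range"
    if (is.null(reason)) {
      d_x <- dist_at(x)
      d_up <- dist_at(lv_up)
      d_low <- dist_at(lv_low)
      bad <- vapply(list(d_x, d_up, d_low), inherits, logical(1), "error")
      if (any(bad)) reason <- "missing isodose surface"
    }
    if (is.null(reason)) {
      bc_up <- brayCurtis(pairHistograms(d_x, d_up, level = x),
                          normalize = normalize)
      bc_low <- brayCurtis(pairHistograms(d_x, d_low, level = x),
                           normalize = normalize)
      if (bc_up <= 0 || bc_low <= 0) reason <- "zero tolerance limit"
    }
    if (!is.null(reason)) {
      warning(sprintf("level %g%%: tolerance limit unavailable (%s)",
                      x, reason), call. = FALSE)
      data.frame(level = x, bcLow = NA_real_, bcUp = NA_real_,
                 levelUp = lv_up, levelLow = lv_low, available = FALSE)
    } else {
      data.frame(level = x, bcLow = bc_low, bcUp = bc_up,
                 levelUp = lv_up, levelLow = lv_low, available = TRUE)
    }
  })
  limits <- do.call(rbind, rows)
  new("ToleranceBand", isoMr = iso_mr, deltaUp = iv$deltaUp,
      deltaLow = iv$deltaLow, spatialTol = spatialTol, limits = limits)
}
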