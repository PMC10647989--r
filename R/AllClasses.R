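#' @import methods
NULL

.check_vec3 <- function(x, what) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    return(sprintf("'%s' must be a finite numeric vector of length 3", what))
  NULL
}

#' DoseGrid: a 3D absorbed-dose distribution
#'
#' Container for a three-dimensional dose grid in absolute units (Gy) with
#' its spatial metadata: per-axis voxel spacing, the patient-coordinate
#' position of the first voxel center, and the plan isocenter used as the
#' parametrization point for isodose shape histograms. Axis order is
#' (x, y, z) with voxel-center convention; all lengths are millimetres.
#'
#' @slot values 3D numeric array of dose in Gy, all values >= 0.
#' @slot spacing numeric(3), voxel size per axis in mm, strictly positive.
#' @slot origin numeric(3), position of voxel (1,1,1)'s center in mm.
#' @slot isocenter numeric(3), parametrization point in mm.
#'
#' @seealso [DoseGrid()], [PercentDoseGrid-class], [toPercent()]
#' @export
setClass("DoseGrid",
  representation(
    values = "array",
    spacing = "numeric",
    origin = "numeric",
    isocenter = "numeric"
  )
)

setValidity("DoseGrid", function(object) {
  msgs <- character()
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 3L)
    msgs <- c(msgs, "'values' must be a 3D numeric array")
  else {
    if (any(!is.finite(v))) msgs <- c(msgs, "'values' must be finite")
    else if (any(v < 0)) msgs <- c(msgs, "dose values must be non-negative")
  }
  for (w in c("spacing", "origin", "isocenter")) {
    m <- .check_vec3(slot(object, w), w)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (!length(msgs) && any(object@spacing <= 0))
    msgs <- c(msgs, "'spacing' must be strictly positive on all axes")
  if (length(msgs)) msgs else TRUE
})

#' PercentDoseGrid: a dose grid in percent of a normalization dose
#'
#' A [DoseGrid-class] whose values are expressed in percent. With the
#' default global-max normalization the maximum voxel is exactly 100%;
#' with explicit-dose normalization values may exceed 100 (an evaluated
#' distribution hotter than its reference), so the class only enforces
#' non-negativity and finiteness.
#'
#' @seealso [toPercent()]
#' @export
setClass("PercentDoseGrid", contains = "DoseGrid")

setValidity("PercentDoseGrid", function(object) {
  if (max(object@values) <= 0)
    "a percent dose grid must contain at least one positive voxel"
  else TRUE
})

#' IsodoseSurface: point set of a single isodose shell
#'
#' Sub-voxel vertices of the closed surface at a given percent dose level,
#' extracted by linear interpolation along grid edges that cross the level
#' (the marching-cubes vertex set). Positions are patient coordinates (mm).
#'
#' @slot level isodose level in percent.
#' @slot points n x 3 numeric matrix of vertex positions (mm).
#' @slot source one of "reference", "evaluated", "unspecified".
#' @export
setClass("IsodoseSurface",
  representation(level = "numeric", points = "matrix", source = "character")
)

setValidity("IsodoseSurface", function(object) {
  msgs <- character()
  if (length(object@level) != 1L || !is.finite(object@level) || object@level <= 0)
    msgs <- c(msgs, "'level' must be a single positive number")
  if (!is.numeric(object@points) || ncol(object@points) != 3L)
    msgs <- c(msgs, "'points' must be an n x 3 numeric matrix")
  else if (nrow(object@points) < 1L)
    msgs <- c(msgs, "surface must contain at least one point")
  if (!object@source %in% c("reference", "evaluated", "unspecified"))
    msgs <- c(msgs, "'source' must be reference/evaluated/unspecified")
  if (length(msgs)) msgs else TRUE
})

#' ShapeHistogram: the distance histogram of an isodose surface
#'
#' Histogram of Euclidean distances of an isodose surface's points from a
#' parametrization point (normally the isocenter) -- the surface's shape
#' signature. The number of bins defaults to Doane's formula applied to the
#' distance sample. The median is taken from the raw (unbinned) distances
#' so the hotter/cooler sign decision is free of binning artifacts.
#'
#' @slot level isodose level (%).
#' @slot breaks ascending bin edges (mm).
#' @slot counts per-bin frequencies; \code{sum(counts) == nPoints}.
#' @slot nPoints sample size.
#' @slot medianDistance median of the raw distances (mm).
#' @slot degenerate TRUE when the sample had zero spread (single bin).
#' @export
setClass("ShapeHistogram",
  representation(
    level = "numeric",
    breaks = "numeric",
    counts = "numeric",
    nPoints = "integer",
    medianDistance = "numeric",
    degenerate = "logical"
  )
)

setValidity("ShapeHistogram", function(object) {
  msgs <- character()
  if (length(object@breaks) < 2L || is.unsorted(object@breaks, strictly = TRUE))
    msgs <- c(msgs, "'breaks' must be >= 2 strictly ascending edges")
  if (length(object@counts) != length(object@breaks) - 1L)
    msgs <- c(msgs, "length(counts) must equal length(breaks) - 1")
  if (any(object@counts < 0))
    msgs <- c(msgs, "'counts' must be non-negative")
  if (!length(msgs) && abs(sum(object@counts) - object@nPoints) > 1e-8)
    msgs <- c(msgs, "sum(counts) must equal nPoints")
  if (length(msgs)) msgs else TRUE
})

#' HistogramPair: reference and evaluated histograms on shared bin edges
#'
#' Bin-wise comparison (and hence Bray-Curtis dissimilarity) is only
#' meaningful on a common set of edges; the pair constructor bins both
#' distance samples on edges whose count comes from the reference sample's
#' Doane formula and whose span covers the union of both samples.
#'
#' @slot reference,evaluated [ShapeHistogram-class] objects on identical edges.
#' @export
setClass("HistogramPair",
  representation(reference = "ShapeHistogram", evaluated = "ShapeHistogram")
)

setValidity("HistogramPair", function(object) {
  r <- object@reference@breaks
  e <- object@evaluated@breaks
  if (length(r) != length(e) || any(abs(r - e) > 1e-9))
    "reference and evaluated histograms must share identical bin edges"
  else TRUE
})

#' RadiusCurve: equivalent-sphere radii of all percent isodoses
#'
#' For levels 1..100 in 1% steps: the volume enclosed by each isodose, the
#' radius of the equivalent sphere, and the radius difference between
#' successive isodoses -- a measure of the local dose gradient of the plan.
#' Radii are made non-increasing by isotonic clipping before differencing.
#'
#' @slot levels integer levels (%).
#' @slot volumes enclosed volumes (mm^3), non-increasing.
#' @slot radii equivalent-sphere radii (mm), non-increasing.
#' @slot radiusDiffs r(level-1) - r(level) (mm); NA at the first level.
#' @export
setClass("RadiusCurve",
  representation(
    levels = "numeric",
    volumes = "numeric",
    radii = "numeric",
    radiusDiffs = "numeric"
  )
)

setValidity("RadiusCurve", function(object) {
  n <- length(object@levels)
  msgs <- character()
  if (length(object@volumes) != n || length(object@radii) != n ||
      length(object@radiusDiffs) != n)
    msgs <- c(msgs, "all slots must have equal length")
  else {
    if (any(diff(object@radii) > 1e-9))
      msgs <- c(msgs, "radii must be non-increasing with level")
    if (any(object@radiusDiffs < -1e-9, na.rm = TRUE))
      msgs <- c(msgs, "radius differences must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' ToleranceBand: plan-specific per-isodose acceptance limits
#'
#' The reference isodose ISOmr is picked at the midrange of the
#' successive-isodose radius differences; the +/- 1 mm MLC QA criterion is
#' mapped through the local gradient at ISOmr to a fixed dose interval
#' (deltaLow, deltaUp), which is applied universally so that each evaluated
#' isodose x gets its own Bray-Curtis acceptance limits from comparing
#' his_x(ref) against his_{x+deltaUp}(ref) and his_{x-deltaLow}(ref).
#' Limits are derived from the reference distribution alone.
#'
#' @slot isoMr reference isodose level (%).
#' @slot deltaUp,deltaLow dose offsets (percentage points), both > 0.
#' @slot spatialTol the spatial criterion (mm) the band was derived from.
#' @slot limits data.frame with columns level, bcLow, bcUp, available.
#' @export
setClass("ToleranceBand",
  representation(
    isoMr = "numeric",
    deltaUp = "numeric",
    deltaLow = "numeric",
    spatialTol = "numeric",
    limits = "data.frame"
  )
)

setValidity("ToleranceBand", function(object) {
  msgs <- character()
  if (object@deltaUp <= 0 || object@deltaLow <= 0)
    msgs <- c(msgs, "'deltaUp' and 'deltaLow' must be strictly positive")
  need <- c("level", "bcLow", "bcUp", "available")
  if (!all(need %in% names(object@limits)))
    msgs <- c(msgs, "limits must have columns level, bcLow, bcUp, available")
  else {
    ok <- object@limits$available
    if (any(ok & (object@limits$bcLow <= 0 | object@limits$bcUp <= 0)))
      msgs <- c(msgs, "available limit pairs must be strictly positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' IsdCurve: the signed normalized isodose-surface-difference chart
#'
#' One entry per evaluated isodose level: the raw Bray-Curtis dissimilarity
#' between reference and evaluated shape histograms, the medians that decide
#' the hotter (+) / cooler (-) sign, the tolerance limit used, and the
#' normalized ISD in percent (+/-100% marks the acceptance boundary).
#' Levels above ISOmr belong to the PTV region, the rest to Normal Tissue.
#'
#' @slot entries data.frame, one row per level (see [as.data.frame()]).
#' @slot isoMr reference isodose (%).
#' @slot deltaUp,deltaLow the tolerance dose interval (percentage points).
#' @slot meanAbsIsd mean of |ISD%| over levels with valid limits.
#' @slot rotation a [RotationCheckResult-class] or NULL.
#' @export
setClass("IsdCurve",
  representation(
    entries = "data.frame",
    isoMr = "numeric",
    deltaUp = "numeric",
    deltaLow = "numeric",
    meanAbsIsd = "numeric",
    rotation = "ANY"
  )
)

setValidity("IsdCurve", function(object) {
  need <- c("level", "bc", "bcUp", "bcLow", "medianRef", "medianEval",
            "sign", "isdPercent", "limitUsed", "region", "withinTolerance")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(object@entries$level))
    return("entries must be sorted by level")
  TRUE
})

#' RotationCheckResult: pre-flight check for rotations about the isocenter
#'
#' Distance histograms taken from the isocenter are blind to rotations of
#' the evaluated distribution about that point. The check recomputes the
#' Bray-Curtis comparison at a set of isodoses from three random
#' non-coplanar probe points in addition to the isocenter: a rotation shows
#' BC ~ 0 at the isocenter but BC > epsilon at some probe point.
#'
#' @slot levelsChecked isodose levels tested (%).
#' @slot probePoints 3 x 3 matrix, one probe point per row (mm).
#' @slot isocenter the parametrization point (mm).
#' @slot bcMatrix length(levels) x 4 matrix of BC values
#'   (columns: isocenter, probe1..3).
#' @slot rotationSuspected logical verdict.
#' @slot epsilon BC threshold used for "zero" vs "nonzero".
#' @slot seed RNG seed used for the probe draw.
#' @export
setClass("RotationCheckResult",
  representation(
    levelsChecked = "numeric",
    probePoints = "matrix",
    isocenter = "numeric",
    bcMatrix = "matrix",
    rotationSuspected = "logical",
    epsilon = "numeric",
    seed = "integer"
  )
)

#' GammaResult: global gamma-index comparison
#'
#' Standard global-normalization gamma analysis: per reference voxel above
#' the low-dose cutoff, the minimum over nearby evaluated positions of
#' sqrt((dose difference / criterion)^2 + (distance / DTA)^2). Pass when the
#' percentage of voxels with gamma <= 1 reaches the acceptance threshold.
#'
#' @slot doseCriterion dose-difference criterion (% of normalization dose).
#' @slot dta distance-to-agreement criterion (mm).
#' @slot lowDoseCutoff cutoff (% of normalization dose) below which voxels
#'   are excluded.
#' @slot normalizationDose the global normalization dose (Gy).
#' @slot gammaMap 3D array of gamma values (NA below cutoff).
#' @slot passingRate percent of evaluated voxels with gamma <= 1.
#' @slot acceptanceThreshold passing-rate threshold (%).
#' @slot pass logical verdict.
#' @export
setClass("GammaResult",
  representation(
    doseCriterion = "numeric",
    dta = "numeric",
    lowDoseCutoff = "numeric",
    normalizationDose = "numeric",
    gammaMap = "array",
    passingRate = "numeric",
    acceptanceThreshold = "numeric",
    pass = "logical"
  )
)

setValidity("GammaResult", function(object) {
  msgs <- character()
  if (any(object@gammaMap < 0, na.rm = TRUE))
    msgs <- c(msgs, "gamma values must be non-negative")
  if (object@passingRate < 0 || object@passingRate > 100)
    msgs <- c(msgs, "passing rate must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' ComparisonReport: full end-to-end comparison result
#'
#' Everything the pipeline produced for one reference/evaluated pair: the
#' ISD curve, the tolerance band, the rotation pre-flight result, the gamma
#' baseline, the configuration echo, and per-level plus overall verdicts.
#' The report reconstructs the ISD chart without re-running the pipeline.
#'
#' @slot inputs list of input descriptions (paths or object labels).
#' @slot config list echoing the configuration used.
#' @slot curve [IsdCurve-class].
#' @slot band [ToleranceBand-class].
#' @slot gamma a [GammaResult-class] or NULL.
#' @slot verdict overall logical verdict (all levels within +/-100% and no
#'   rotation suspected).
#' @export
setClass("ComparisonReport",
  representation(
    inputs = "list",
    config = "list",
    curve = "IsdCurve",
    band = "ToleranceBand",
    gamma = "ANY",
    verdict = "logical"
  )
)
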