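#' Construct a dose grid
#'
#' @param values 3D numeric array of dose (Gy for [DoseGrid()], percent for
#'   [PercentDoseGrid()]).
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) position of the first voxel center (mm).
#'   Defaults to centering the grid on the coordinate origin.
#' @param isocenter numeric(3) parametrization point (mm). Defaults to the
#'   geometric center of the grid. A warning (not an error) is issued when it
#'   lies outside the grid's bounding box, since off-grid parametrization
#'   points are legal but usually a mistake.
#' @return a [DoseGrid-class] (resp. [PercentDoseGrid-class]).
#' @examples
#' g <- DoseGrid(array(1, c(5, 5, 5)), spacing = c(1, 1, 1))
#' doseMax(g)
#' @export
DoseGrid <- function(values, spacing = c(1, 1, 1), origin = NULL,
                     isocenter = NULL) {
  values <- .as_dose_array(values)
  d <- dim(values)
  if (is.null(origin)) origin <- -(d - 1) * spacing / 2
  if (is.null(isocenter)) isocenter <- origin + (d - 1) * spacing / 2
  obj <- new("DoseGrid", values = values, spacing = as.numeric(spacing),
             origin = as.numeric(origin), isocenter = as.numeric(isocenter))
  .warn_isocenter_outside(obj)
  obj
}

#' @rdname DoseGrid
#' @export
PercentDoseGrid <- function(values, spacing = c(1, 1, 1), origin = NULL,
                            isocenter = NULL) {
  values <- .as_dose_array(values)
  d <- dim(values)
  if (is.null(origin)) origin <- -(d - 1) * spacing / 2
  if (is.null(isocenter)) isocenter <- origin + (d - 1) * spacing / 2
  obj <- new("PercentDoseGrid", values = values,
             spacing = as.numeric(spacing),
             origin = as.numeric(origin), isocenter = as.numeric(isocenter))
  .warn_isocenter_outside(obj)
  obj
}

.as_dose_array <- function(values) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  values
}

.warn_isocenter_outside <- function(grid) {
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (dim(grid@values) - 1) * grid@spacing + grid@spacing / 2
  if (any(grid@isocenter < lo | grid@isocenter > hi))
    warning("isocenter lies outside the grid bounding box", call. = FALSE)
  invisible(grid)
}

#' Convert a dose grid to percent of a normalization dose
#'
#' The default normalizes each distribution to its own maximum dose
#' ("global_max"), so the hottest voxel is exactly 100%. An explicit
#' normalization dose (e.g. the prescription dose, or the reference
#' maximum when comparing two plans on a common scale) can be supplied
#' instead, in which case values above 100% are possible.
#'
#' @param grid a [DoseGrid-class].
#' @param normalization "global_max" or "explicit_dose".
#' @param dose normalization dose in Gy, required for "explicit_dose".
#' @return a [PercentDoseGrid-class].
#' @examples
#' g <- DoseGrid(array(seq(0, 2, length.out = 27), c(3, 3, 3)))
#' max(doseValues(toPercent(g)))  # 100
#' @export
toPercent <- function(grid, normalization = c("global_max", "explicit_dose"),
                      dose = NULL) {
  stopifnot(is(grid, "DoseGrid"))
  normalization <- match.arg(normalization)
  ref <- if (normalization == "global_max") {
    dm <- max(grid@values)
    if (dm <= 0) stop("cannot normalize: grid maximum dose is not positive")
    dm
  } else {
    if (is.null(dose) || !is.finite(dose) || dose <= 0)
      stop("explicit normalization requires a positive 'dose' (Gy)")
    dose
  }
  new("PercentDoseGrid", values = grid@values / ref * 100,
      spacing = grid@spacing, origin = grid@origin,
      isocenter = grid@isocenter)
}

## ---- accessors -------------------------------------------------------------

#' @rdname accessors
setMethod("doseValues", "DoseGrid", function(object) object@values)

#' @rdname accessors
setMethod("gridSpacing", "DoseGrid", function(object) object@spacing)

#' @rdname accessors
setMethod("gridOrigin", "DoseGrid", function(object) object@origin)

#' @rdname accessors
setMethod("isocenter", "DoseGrid", function(object) object@isocenter)

#' @rdname accessors
setMethod("doseMax", "DoseGrid", function(object) max(object@values))

#' @rdname accessors
setMethod("isoLevel", "IsodoseSurface", function(object) object@level)

#' @rdname accessors
setMethod("surfacePoints", "IsodoseSurface", function(object) object@points)

#' @rdname accessors
setMethod("isoLevel", "ShapeHistogram", function(object) object@level)

#' @rdname accessors
setMethod("binEdges", "ShapeHistogram", function(object) object@breaks)

#' @rdname accessors
setMethod("binCounts", "ShapeHistogram", function(object) object@counts)

#' @rdname accessors
setMethod("medianDistance", "ShapeHistogram",
          function(object) object@medianDistance)

#' @rdname accessors
setMethod("isoMr", "ToleranceBand", function(object) object@isoMr)

#' @rdname accessors
setMethod("isoMr", "IsdCurve", function(object) object@isoMr)

#' @rdname accessors
setMethod("meanAbsIsd", "IsdCurve", function(object) object@meanAbsIsd)

#' @rdname accessors
setMethod("passingRate", "GammaResult", function(object) object@passingRate)

#' @rdname accessors
setMethod("rotationSuspected", "RotationCheckResult",
          function(object) object@rotationSuspected)

## ---- coercion --------------------------------------------------------------

#' @export
setMethod("as.data.frame", "RadiusCurve", function(x, ...) {
  data.frame(level = x@levels, volume = x@volumes, radius = x@radii,
             radiusDiff = x@radiusDiffs)
})

#' @export
setMethod("as.data.frame", "IsdCurve", function(x, ...) x@entries)

#' @export
setMethod("as.data.frame", "ToleranceBand", function(x, ...) x@limits)

## ---- show ------------------------------------------------------------------

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s %dx%dx%d voxels, spacing %s mm\n", class(object),
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = "x")))
  unit <- if (is(object, "PercentDoseGrid")) "%" else "Gy"
  cat(sprintf("  max %s %s, isocenter (%s) mm\n",
              format(max(object@values), digits = 5), unit,
              paste(format(object@isocenter, digits = 4), collapse = ", ")))
})

setMethod("show", "IsodoseSurface", function(object) {
  cat(sprintf("IsodoseSurface at %g%% (%s): %d points\n", object@level,
              object@source, nrow(object@points)))
})

setMethod("show", "ShapeHistogram", function(object) {
  cat(sprintf(
    "ShapeHistogram at %g%%: %d points in %d bins [%.2f, %.2f] mm, median %.2f mm\n",
    object@level, object@nPoints, length(object@counts),
    min(object@breaks), max(object@breaks), object@medianDistance))
})

setMethod("show", "ToleranceBand", function(object) {
  cat(sprintf(
    "ToleranceBand: ISOmr %g%%, dose interval -%.2f/+%.2f pct points (%.1f mm criterion)\n",
    object@isoMr, object@deltaLow, object@deltaUp, object@spatialTol))
  av <- object@limits$available
  cat(sprintf("  limits for %d/%d evaluated levels\n", sum(av), length(av)))
})

setMethod("show", "IsdCurve", function(object) {
  e <- object@entries
  cat(sprintf("IsdCurve: %d levels, ISOmr %g%%, mean |ISD| %.1f%%\n",
              nrow(e), object@isoMr, object@meanAbsIsd))
  n_out <- sum(!e$withinTolerance)
  cat(sprintf("  %d level(s) outside +/-100%% tolerance\n", n_out))
  if (!is.null(object@rotation))
    cat(sprintf("  rotation pre-flight: %s\n",
                if (object@rotation@rotationSuspected) "SUSPECTED" else "clear"))
})

setMethod("show", "RotationCheckResult", function(object) {
  cat(sprintf("RotationCheckResult: levels %s, rotation %s (eps %.0e, seed %d)\n",
              paste(object@levelsChecked, collapse = "/"),
              if (object@rotationSuspected) "SUSPECTED" else "not suspected",
              object@epsilon, object@seed))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult %g%%/%g mm (cutoff %g%%): passing rate %.1f%% -> %s\n",
              object@doseCriterion, object@dta, object@lowDoseCutoff,
              object@passingRate, if (object@pass) "PASS" else "FAIL"))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  show(object@curve)
  if (!is.null(object@gamma)) show(object@gamma)
  cat(sprintf("  overall verdict: %s\n",
              if (object@verdict) "PASS" else "FAIL"))
})
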