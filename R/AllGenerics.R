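#' Accessors for dose grids and derived objects
#'
#' @param object an object of one of the package's classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("doseValues", function(object) standardGeneric("doseValues"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("isocenter", function(object) standardGeneric("isocenter"))

#' @rdname accessors
#' @export
setGeneric("doseMax", function(object) standardGeneric("doseMax"))

#' @rdname accessors
#' @export
setGeneric("isoLevel", function(object) standardGeneric("isoLevel"))

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(object) standardGeneric("surfacePoints"))

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setGeneric("medianDistance", function(object) standardGeneric("medianDistance"))

#' @rdname accessors
#' @export
setGeneric("isoMr", function(object) standardGeneric("isoMr"))

#' @rdname accessors
#' @export
setGeneric("meanAbsIsd", function(object) standardGeneric("meanAbsIsd"))

#' @rdname accessors
#' @export
setGeneric("passingRate", function(object) standardGeneric("passingRate"))

#' @rdname accessors
#' @export
setGeneric("rotationSuspected",
           function(object) standardGeneric("rotationSuspected"))

#' Bray-Curtis dissimilarity
#'
#' @param e,r either a [HistogramPair-class] (with \code{r} missing) or two
#'   numeric count vectors on shared bin edges.
#' @param normalize scale each histogram to unit sum (relative frequencies)
#'   before comparing, so unequal sample sizes do not masquerade as shape
#'   difference. Default TRUE.
#' @return dissimilarity in [0, 1]; 0 means identical binned shapes, 1 means
#'   disjoint support.
#' @export
setGeneric("brayCurtis", function(e, r, normalize = TRUE)
  standardGeneric("brayCurtis"))
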