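#' Doane's formula for the number of histogram bins
#'
#' bins = ceil(1 + log2(n) + log2(1 + |g1| / sigma_g1)) where g1 is the
#' adjusted Fisher-Pearson sample skewness of the distances and
#' sigma_g1 = sqrt(6 (n - 2) / ((n + 1)(n + 3))). Doane's rule widens the
#' Sturges count for skewed samples, which distance distributions of
#' irregular isodose surfaces typically are. A floor of 4 bins is applied;
#' a zero-variance sample returns a single bin flagged as degenerate.
#'
#' @param distances numeric distance sample, n >= 4.
#' @return integer bin count; attribute \code{degenerate = TRUE} when the
#'   sample has zero spread.
#' @examples
#' x <- rep(c(-1, 1), 512) + 5  # symmetric, n = 1024 -> 11 bins
#' doaneBinCount(x)
#' @export
doaneBinCount <- function(distances) {
  d <- as.numeric(distances)
  n <- length(d)
  if (n < 4L) stop("Doane's formula needs at least 4 observations")
  if (max(d) - min(d) <= 0)
    return(structure(1L, degenerate = TRUE))
  g1 <- .adjusted_skewness(d)
  sigma <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  k <- ceiling(1 + log2(n) + log2(1 + abs(g1) / sigma))
  max(as.integer(k), 4L)
}

## Adjusted Fisher-Pearson sample skewness: b1 * sqrt(n(n-1)) / (n-2).
.adjusted_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 <= 0) return(0)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Build the shape histogram of a distance sample
#'
#' Bins the distances on Doane-derived equal-width edges spanning the
#' sample range, or on caller-supplied shared edges. The median is always
#' computed from the raw (unbinned) distances, keeping the hotter/cooler
#' sign decision free of binning artifacts. Counts conserve the sample size
#' (values falling outside supplied edges are counted in the terminal bins).
#'
#' @param distances numeric distances (mm), e.g. from
#'   [distancesFromPoint()]; a \code{level} attribute is honoured.
#' @param edges optional ascending bin edges (mm) shared with another
#'   histogram.
#' @param level isodose level stored on the histogram (defaults to the
#'   sample's \code{level} attribute, or NA).
#' @return a [ShapeHistogram-class].
#' @examples
#' h <- buildShapeHistogram(c(1, 1, 3, 3), edges = c(0, 2, 4))
#' binCounts(h)       # 2 2
#' medianDistance(h)  # 2
#' @export
buildShapeHistogram <- function(distances, edges = NULL, level = NULL) {
  d <- as.numeric(distances)
  if (!length(d)) stop("empty distance sample")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  if (is.null(level))
    level <- attr(distances, "level") %||% NA_real_
  degenerate <- FALSE
  if (is.null(edges)) {
    if (length(d) < 4L) stop("need >= 4 distances to derive bin edges")
    k <- doaneBinCount(d)
    if (isTRUE(attr(k, "degenerate"))) {
      degenerate <- TRUE
      edges <- d[1] + c(-0.5, 0.5)
    } else {
      edges <- seq(min(d), max(d), length.out = k + 1L)
    }
  } else {
    edges <- as.numeric(edges)
    if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
      stop("'edges' must be strictly ascending with >= 2 values")
  }
  idx <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  new("ShapeHistogram", level = as.numeric(level), breaks = edges,
      counts = as.numeric(counts), nPoints = length(d),
      medianDistance = stats::median(d), degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin a reference and an evaluated distance sample on shared edges
#'
#' The bin count comes from Doane's formula applied to the reference
#' sample (anchoring the edge policy to the reference keeps tolerance
#' limits and evaluation comparisons on the same footing); the edge span
#' covers the union of both samples so no mass is lost.
#'
#' @param refDistances,evalDistances numeric distance samples (mm).
#' @param level isodose level stored on both histograms.
#' @return a [HistogramPair-class].
#' @export
pairHistograms <- function(refDistances, evalDistances, level = NULL) {
  r <- as.numeric(refDistances)
  e <- as.numeric(evalDistances)
  if (!length(r) || !length(e)) stop("both distance samples must be non-empty")
  if (is.null(level))
    level <- attr(refDistances, "level") %||% NA_real_
  k <- doaneBinCount(r)
  lo <- min(r, e)
  hi <- max(r, e)
  if (hi - lo <= 0) {
    edges <- lo + c(-0.5, 0.5)
  } else {
    if (isTRUE(attr(k, "degenerate"))) k <- 1L
    edges <- seq(lo, hi, length.out = k + 1L)
  }
  new("HistogramPair",
      reference = buildShapeHistogram(r, edges = edges, level = level),
      evaluated = buildShapeHistogram(e, edges = edges, level = level))
}

#' @rdname brayCurtis
setMethod("brayCurtis", signature(e = "HistogramPair", r = "missing"),
  function(e, r, normalize = TRUE) {
    brayCurtis(e@evaluated@counts, e@reference@counts, normalize = normalize)
  })

#' @rdname brayCurtis
setMethod("brayCurtis", signature(e = "numeric", r = "numeric"),
  function(e, r, normalize = TRUE) {
    if (length(e) != length(r))
      stop("histograms must be binned on identical edges")
    if (any(e < 0) || any(r < 0)) stop("counts must be non-negative")
    if (sum(e) == 0 && sum(r) == 0)
      stop("Bray-Curtis undefined for two all-zero histograms")
    if (normalize) {
      if (sum(e) == 0 || sum(r) == 0)
        stop("cannot normalize an all-zero histogram")
      e <- e / sum(e)
      r <- r / sum(r)
    }
    sum(abs(e - r)) / sum(e + r)
  })
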