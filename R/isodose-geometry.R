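#' Extract an isodose surface from a percent dose grid
#'
#' Finds all sub-voxel crossings of the iso-value along grid edges: for
#' every pair of adjacent voxels whose values straddle \code{level}, the
#' crossing position is linearly interpolated. This is the marching-cubes
#' vertex set of the isosurface (no mesh topology is built -- the shape
#' histogram only needs the point cloud). With \code{method = "voxel"} the
#' centers of voxels at >= level that touch a voxel below level are returned
#' instead (a voxel-membership shell, kept for sensitivity studies).
#'
#' @param grid a [PercentDoseGrid-class].
#' @param level isodose level in percent, 0 < level <= 100 for global-max
#'   normalized grids (levels above the grid maximum raise a
#'   missing-isodose error).
#' @param source label stored on the surface ("reference", "evaluated",
#'   "unspecified").
#' @param method "interpolated" (default, sub-voxel) or "voxel".
#' @return an [IsodoseSurface-class]. Surfaces with fewer than 4 points are
#'   rejected as missing: histograms and medians are meaningless below that
#'   size.
#' @examples
#' g <- toPercent(makePlan(shape = "sphere", r0 = 20, gridDim = rep(45, 3)))
#' s <- extractIsodoseSurface(g, 50)
#' range(distancesFromPoint(s, isocenter(g)))  # all close to 10 mm
#' @export
extractIsodoseSurface <- function(grid, level, source = "unspecified",
                                  method = c("interpolated", "voxel")) {
  stopifnot(is(grid, "PercentDoseGrid"))
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level <= 0)
    stop("'level' must be a single positive percent value")
  v <- grid@values
  if (level > max(v))
    stop(sprintf("missing isodose: level %g%% exceeds grid maximum %.4g%%",
                 level, max(v)))
  pts <- if (method == "interpolated") .edge_crossings(grid, level)
         else .voxel_shell(grid, level)
  if (nrow(pts) < 4L)
    stop(sprintf(
      "missing isodose: level %g%% yields a degenerate surface (%d points)",
      level, nrow(pts)))
  new("IsodoseSurface", level = level, points = pts, source = source)
}

.axis_slab <- function(v, ax, range) {
  switch(ax,
         v[range, , , drop = FALSE],
         v[, range, , drop = FALSE],
         v[, , range, drop = FALSE])
}

## Edge-crossing vertices along each axis, vectorized per axis slab.
.edge_crossings <- function(grid, level) {
  v <- grid@values
  d <- dim(v)
  sp <- grid@spacing
  or <- grid@origin
  out <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    a <- .axis_slab(v, ax, 1:(n - 1L))
    b <- .axis_slab(v, ax, 2:n)
    cross <- (a >= level) != (b >= level)
    if (!any(cross)) next
    w <- which(cross)
    t <- (level - a[w]) / (b[w] - a[w])
    ijk <- arrayInd(w, dim(a)) - 1L  # zero-based voxel index of the lower end
    pos <- sweep(ijk * rep(sp, each = nrow(ijk)), 2L, or, "+")
    pos[, ax] <- pos[, ax] + t * sp[ax]
    out[[ax]] <- pos
  }
  pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pts)) pts <- matrix(numeric(), ncol = 3L)
  colnames(pts) <- c("x", "y", "z")
  pts
}

.voxel_shell <- function(grid, level) {
  v <- grid@values
  d <- dim(v)
  inside <- v >= level
  ## boundary voxels: inside with at least one 6-neighbour outside (or on
  ## the grid border, where the neighbour counts as outside)
  interior <- inside
  for (ax in 1:3) {
    n <- d[ax]
    nb_plus <- array(FALSE, d)
    nb_minus <- array(FALSE, d)
    if (n >= 2L) switch(ax, {
      nb_plus[1:(n - 1L), , ] <- inside[2:n, , ]
      nb_minus[2:n, , ] <- inside[1:(n - 1L), , ]
    }, {
      nb_plus[, 1:(n - 1L), ] <- inside[, 2:n, ]
      nb_minus[, 2:n, ] <- inside[, 1:(n - 1L), ]
    }, {
      nb_plus[, , 1:(n - 1L)] <- inside[, , 2:n]
      nb_minus[, , 2:n] <- inside[, , 1:(n - 1L)]
    })
    interior <- interior & nb_plus & nb_minus
  }
  w <- which(inside & !interior)
  if (!length(w)) return(matrix(numeric(), ncol = 3L))
  ijk <- arrayInd(w, d) - 1L
  pos <- sweep(ijk * rep(grid@spacing, each = nrow(ijk)), 2L,
               grid@origin, "+")
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Euclidean distances of surface points from a parametrization point
#'
#' @param surface an [IsodoseSurface-class].
#' @param point numeric(3) position in mm (normally the isocenter).
#' @return numeric vector of distances (mm), one per surface point and in
#'   point order, with attributes \code{level} and \code{point}.
#' @examples
#' s <- new("IsodoseSurface", level = 50,
#'          points = rbind(c(3, 4, 0)), source = "unspecified")
#' distancesFromPoint(s, c(0, 0, 0))  # 5
#' @export
distancesFromPoint <- function(surface, point) {
  stopifnot(is(surface, "IsodoseSurface"))
  if (!is.numeric(point) || length(point) != 3L)
    stop("'point' must be a numeric vector of length 3")
  p <- surface@points
  d <- sqrt((p[, 1] - point[1])^2 + (p[, 2] - point[2])^2 +
            (p[, 3] - point[3])^2)
  structure(d, level = surface@level, point = as.numeric(point))
}

#' Volume enclosed by an isodose
#'
#' Voxel-counting volume of the region with dose >= level.
#'
#' @param grid a [PercentDoseGrid-class].
#' @param level isodose level (%).
#' @return volume in mm^3 (0 when no voxel reaches the level).
#' @export
enclosedVolume <- function(grid, level) {
  stopifnot(is(grid, "PercentDoseGrid"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0)
    stop("'level' must be a single positive percent value")
  sum(grid@values >= level) * prod(grid@spacing)
}

#' Radius of the sphere with a given volume
#'
#' @param volume volume in mm^3 (vectorized).
#' @return radius in mm: (3 volume / 4 pi)^(1/3).
#' @export
equivalentRadius <- function(volume) {
  if (any(volume < 0)) stop("'volume' must be non-negative")
  (3 * volume / (4 * pi))^(1 / 3)
}

#' Equivalent-sphere radius curve over all percent isodoses
#'
#' For levels 1..100 (1% increments) computes the enclosed volume, the
#' equivalent-sphere radius, and the radius difference between successive
#' isodoses -- the plan's local dose-gradient profile from which the
#' tolerance band is derived. Radii are clipped to be non-increasing
#' (isotonic, via a running minimum) before differencing so voxelization
#' noise cannot produce negative differences.
#'
#' @param grid a [PercentDoseGrid-class] normalized so its maximum is 100.
#' @return a [RadiusCurve-class].
#' @export
buildRadiusCurve <- function(grid) {
  stopifnot(is(grid, "PercentDoseGrid"))
  levels <- 1:100
  vs <- sort.int(as.vector(grid@values))
  n <- length(vs)
  ## count of voxels >= L  =  n - count(< L)
  n_ge <- n - findInterval(levels - 1e-9, vs)
  volumes <- n_ge * prod(grid@spacing)
  radii <- cummin(equivalentRadius(volumes))
  diffs <- c(NA_real_, -diff(radii))
  new("RadiusCurve", levels = as.numeric(levels), volumes = volumes,
      radii = radii, radiusDiffs = diffs)
}
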