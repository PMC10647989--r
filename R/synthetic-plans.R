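#' Specification for a synthetic dose distribution
#'
#' Describes a radially structured dose field with analytically known
#' isodose geometry, the stand-in for verification-phantom plans when
#' exercising the comparison pipeline. Shapes: a sphere (radial falloff), an
#' ellipsoid (anisotropic radial falloff along given semi-axis scales), or a
#' two-lobe field (two displaced maxima, a dual-target analogue whose
#' radius-difference curve shows two local maxima). Falloffs: linear
#' (dose = dMax (1 - s / r0)), quadratic (dMax (1 - (s / r0)^2)), or
#' sigmoid (logistic shoulder at r0 / 2 with width \code{sigmoidWidth},
#' rescaled so the center is dMax).
#'
#' Defaults emulate the verification conditions the pipeline targets: a
#' 1 x 1 x 1 mm dose grid, a falloff scale r0 = 50 mm (a prostate-like
#' high-dose region inside a phantom), dMax = 2 Gy (a typical fraction
#' dose), isocenter at the field center.
#'
#' @param shape "sphere", "ellipsoid" or "twolobe".
#' @param dMax maximum dose (Gy).
#' @param falloff "linear", "quadratic" or "sigmoid".
#' @param r0 falloff scale (mm): the radius where linear/quadratic falloffs
#'   reach zero.
#' @param sigmoidWidth logistic width (mm) for the sigmoid falloff.
#' @param axes numeric(3) relative semi-axis scales for the ellipsoid.
#' @param orientation rotation of the field about the z axis through the
#'   isocenter, in degrees (analytic -- the rotated field is sampled
#'   directly, with no resampling error).
#' @param gridDim numeric(3) voxel counts; default covers 2.3 r0 per axis.
#' @param spacing numeric(3) voxel size (mm), default 1 mm isotropic.
#' @param isocenterOffset numeric(3), position of the parametrization point
#'   relative to the field center (mm). Zero keeps the isocenter at the
#'   dose centroid; a nonzero offset emulates the clinical situation where
#'   the isocenter is merely central, not coincident with the dose maximum,
#'   and gives every isodose's distance histogram a nonzero intrinsic width
#'   (a perfectly centered sphere is the degenerate case whose histograms
#'   collapse to a single distance).
#' @param lobeOffset center-to-center distance of the two lobes (mm).
#' @param lobeFraction dMax fraction of the secondary lobe.
#' @param seed kept for config compatibility; the generator is
#'   deterministic and draws no random numbers.
#' @return a list of class \code{planSpec}.
#' @seealso [makePlan()], [analyticIsodoseRadius()]
#' @export
planSpec <- function(shape = c("sphere", "ellipsoid", "twolobe"),
                     dMax = 2, falloff = c("linear", "quadratic", "sigmoid"),
                     r0 = 50, sigmoidWidth = r0 / 20, axes = c(1, 1, 1),
                     orientation = 0, gridDim = NULL, spacing = c(1, 1, 1),
                     isocenterOffset = c(0, 0, 0),
                     lobeOffset = r0, lobeFraction = 0.8, seed = 1L) {
  shape <- match.arg(shape)
  falloff <- match.arg(falloff)
  if (dMax <= 0) stop("'dMax' must be positive")
  if (r0 <= 0) stop("'r0' must be positive")
  if (any(axes <= 0) || length(axes) != 3L)
    stop("'axes' must be 3 positive scales")
  if (is.null(gridDim)) {
    ext <- if (shape == "twolobe") 2.3 * r0 + lobeOffset else 2.3 * r0
    gridDim <- rep(2 * ceiling(ext * max(axes) / 2) + 1, 3L)
  }
  if (any(gridDim < 9)) stop("grid too small for a meaningful plan")
  if (any((gridDim - 1) * spacing < 1.5 * r0))
    stop("falloff scale incompatible with grid extent")
  structure(list(shape = shape, dMax = dMax, falloff = falloff, r0 = r0,
                 sigmoidWidth = sigmoidWidth, axes = as.numeric(axes),
                 orientation = as.numeric(orientation),
                 gridDim = as.integer(gridDim), spacing = as.numeric(spacing),
                 isocenterOffset = as.numeric(isocenterOffset),
                 lobeOffset = lobeOffset, lobeFraction = lobeFraction,
                 seed = as.integer(seed)),
            class = "planSpec")
}

#' @export
print.planSpec <- function(x, ...) {
  cat(sprintf("planSpec: %s / %s falloff, r0 %g mm, dMax %g Gy, grid %s @ %s mm\n",
              x$shape, x$falloff, x$r0, x$dMax,
              paste(x$gridDim, collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Write or read a plan specification as JSON
#' @param spec a \code{planSpec}.
#' @param path file path.
#' @return \code{readPlanSpec} returns the \code{planSpec}.
#' @export
writePlanSpec <- function(spec, path) {
  stopifnot(inherits(spec, "planSpec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlanSpec
#' @export
readPlanSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(planSpec, x)
}

## 1-D falloff profile: dose fraction (of dMax) at scaled radius s (mm)
.falloff_profile <- function(spec, s) {
  switch(spec$falloff,
    linear = pmax(1 - s / spec$r0, 0),      # arg order keeps dim()
    quadratic = pmax(1 - (s / spec$r0)^2, 0),
    sigmoid = {
      g <- function(u) 1 / (1 + exp((u - spec$r0 / 2) / spec$sigmoidWidth))
      g(s) / g(0)
    })
}

#' Generate a synthetic dose grid from a plan specification
#'
#' Samples the analytic dose field at the voxel centers of a regular grid.
#' The generator is fully deterministic: the same specification always
#' yields a bit-identical grid.
#'
#' @param spec a [planSpec()]; alternatively pass the spec's arguments
#'   directly via \code{...}.
#' @param ... arguments forwarded to [planSpec()] when \code{spec} is NULL.
#' @return a [DoseGrid-class] with the isocenter at the field center.
#' @examples
#' g <- makePlan(shape = "sphere", falloff = "linear", r0 = 20,
#'               gridDim = rep(45, 3))
#' doseMax(g)
#' @export
makePlan <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- planSpec(...)
  stopifnot(inherits(spec, "planSpec"))
  d <- spec$gridDim
  sp <- spec$spacing
  origin <- -(d - 1) * sp / 2  # grid centered on (0,0,0)
  cx <- seq(origin[1], by = sp[1], length.out = d[1])
  cy <- seq(origin[2], by = sp[2], length.out = d[2])
  cz <- seq(origin[3], by = sp[3], length.out = d[3])

  scaled_radius <- function(center) {
    ax <- spec$axes
    if (spec$orientation != 0) {
      ## rotate the (x, y) plane about the isocenter before axis scaling
      th <- spec$orientation * pi / 180
      xy <- expand.grid(x = cx - center[1], y = cy - center[2])
      u <- xy$x * cos(th) + xy$y * sin(th)
      w <- -xy$x * sin(th) + xy$y * cos(th)
      dxy2 <- matrix((u / ax[1])^2 + (w / ax[2])^2,
                     nrow = length(cx))
      dz2 <- ((cz - center[3]) / ax[3])^2
      sqrt(outer(dxy2, dz2, "+"))
    } else {
      dx2 <- ((cx - center[1]) / ax[1])^2
      dy2 <- ((cy - center[2]) / ax[2])^2
      dz2 <- ((cz - center[3]) / ax[3])^2
      sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    }
  }

  values <- if (spec$shape == "twolobe") {
    off <- c(spec$lobeOffset / 2, 0, 0)
    v1 <- spec$dMax * .falloff_profile(spec, scaled_radius(-off))
    v2 <- spec$dMax * spec$lobeFraction *
      .falloff_profile(spec, scaled_radius(off))
    pmax(v1, v2)
  } else {
    spec$dMax * .falloff_profile(spec, scaled_radius(c(0, 0, 0)))
  }
  DoseGrid(values, spacing = sp, origin = origin,
           isocenter = spec$isocenterOffset)
}

#' Analytic isodose radius of a synthetic plan
#'
#' Closed-form (linear, quadratic) or logistic-inversion (sigmoid) radius
#' of the level isosurface along the first semi-axis, for sphere and
#' ellipsoid shapes. For the sphere this is the true isodose radius; for
#' the ellipsoid multiply by \code{prod(axes)^(1/3)} to get the
#' equivalent-sphere radius.
#'
#' @param spec a [planSpec()].
#' @param level isodose level in percent, 0 < level <= 100.
#' @return radius in mm.
#' @examples
#' sp <- planSpec(shape = "sphere", falloff = "linear", r0 = 100,
#'                gridDim = rep(231, 3))
#' analyticIsodoseRadius(sp, 95)  # 5
#' @export
analyticIsodoseRadius <- function(spec, level) {
  stopifnot(inherits(spec, "planSpec"))
  if (!spec$shape %in% c("sphere", "ellipsoid"))
    stop("analytic radius is only defined for sphere/ellipsoid shapes")
  if (any(level <= 0 | level > 100))
    stop("'level' must lie in (0, 100]")
  q <- level / 100
  switch(spec$falloff,
    linear = spec$r0 * (1 - q),
    quadratic = spec$r0 * sqrt(1 - q),
    sigmoid = {
      g0 <- 1 / (1 + exp(-spec$r0 / 2 / spec$sigmoidWidth))
      p <- q * g0
      r <- spec$r0 / 2 + spec$sigmoidWidth * log(1 / p - 1)
      pmax(0, r)
    })
}

#' Rigidly shift a dose field
#'
#' Translates the dose field by \code{shift} (mm) and resamples it onto the
#' original grid with tricubic (Catmull-Rom) interpolation, clipping
#' negative overshoots to zero. The isocenter metadata is left unchanged:
#' the shift models a delivery/setup error against a fixed verification
#' geometry, not a change of registration.
#'
#' @param grid a [DoseGrid-class] or [PercentDoseGrid-class].
#' @param shift numeric(3) translation (mm); its norm must stay below a
#'   quarter of the smallest grid extent.
#' @return a grid of the same class.
#' @export
applyShift <- function(grid, shift) {
  stopifnot(is(grid, "DoseGrid"))
  if (!is.numeric(shift) || length(shift) != 3L)
    stop("'shift' must be a numeric vector of length 3")
  extent <- (dim(grid@values) - 1) * grid@spacing
  if (sqrt(sum(shift^2)) >= min(extent) / 4)
    stop("excessive shift: magnitude must stay below a quarter of the ",
         "grid extent")
  if (all(shift == 0)) return(grid)
  .resample_grid(grid, A = diag(3), b = -as.numeric(shift))
}

#' Rigidly rotate a dose field about its isocenter
#'
#' Rotates the dose field by \code{angle} degrees about the axis through
#' the isocenter and resamples it onto the original grid (tricubic).
#' Used to exercise the rotation pre-flight check, whose isocentric
#' histograms are blind to exactly this transformation.
#'
#' @param grid a [DoseGrid-class] or [PercentDoseGrid-class].
#' @param angle rotation angle in degrees.
#' @param axis "x", "y", "z" or a numeric(3) axis direction.
#' @return a grid of the same class.
#' @export
applyRotation <- function(grid, angle, axis = "z") {
  stopifnot(is(grid, "DoseGrid"))
  if (is.character(axis))
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  if (length(axis) != 3L || sum(axis^2) == 0)
    stop("'axis' must be a non-zero 3-vector or one of \"x\", \"y\", \"z\"")
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  ## value at p comes from the un-rotated field at R^T (p - iso) + iso
  A <- t(R)
  b <- grid@isocenter - A %*% grid@isocenter
  .resample_grid(grid, A = A, b = as.numeric(b))
}

.resample_grid <- function(grid, A, b) {
  v <- .resample_affine(as.vector(grid@values), dim(grid@values),
                        grid@spacing, grid@origin, A, b, fill = 0)
  out <- grid
  out@values <- array(v, dim = dim(grid@values))
  validObject(out)
  out
}
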