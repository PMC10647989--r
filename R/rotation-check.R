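#' Pre-flight check for rotations of the evaluated distribution
#'
#' Shape histograms taken from the isocenter are invariant to any rotation
#' of the distribution about that point, so a purely rotated evaluated plan
#' would compare as a perfect match. The check re-runs the Bray-Curtis
#' comparison at a set of isodoses (default 50/75/80/90%) from three
#' randomly drawn non-coplanar probe points in addition to the isocenter:
#' a rotation leaves the isocentric BC at ~0 while at least one probe point
#' sees BC above the threshold. A plain translation raises the isocentric
#' BC too and is therefore attributed to shape difference, not rotation.
#'
#' Probe points are drawn uniformly inside the bounding box of the
#' reference 50% isodose; non-coplanarity with the isocenter is enforced by
#' a minimum tetrahedron volume, with bounded retries. By default the
#' volume floor is 0.5% of the bounding-box volume (the median draw is
#' about that size): probes clustered near a single line through the
#' isocenter are themselves nearly blind to rotations about that line, so
#' the triplet must subtend a sizeable solid angle.
#'
#' @param ref,eval registered [PercentDoseGrid-class] objects.
#' @param seed integer RNG seed for the probe draw (recorded in the result).
#' @param levels isodose levels to test (%).
#' @param epsilon BC threshold separating "zero" from "nonzero" (default
#'   1e-3 on normalized BC; voxelization makes exact equality unattainable).
#' @param normalize relative-frequency normalization for BC (default TRUE).
#' @param minTetraVolume minimum tetrahedron volume (mm^3) of the probe
#'   triplet with the isocenter; NULL (default) uses 0.5% of the probe
#'   bounding-box volume.
#' @param maxTries probe redraws before giving up.
#' @return a [RotationCheckResult-class].
#' @export
runRotationCheck <- function(ref, eval, seed = 1L,
                             levels = c(50, 75, 80, 90),
                             epsilon = 1e-3, normalize = TRUE,
                             minTetraVolume = NULL, maxTries = 100L) {
  ref <- .as_percent(ref)
  eval <- .as_percent(eval)
  seed <- as.integer(seed)

  ## bounding box of the reference 50% isodose for the probe draw
  s50 <- extractIsodoseSurface(ref, 50, source = "reference")
  box <- apply(s50@points, 2L, range)
  iso <- ref@isocenter
  if (is.null(minTetraVolume))
    minTetraVolume <- 0.005 * prod(box[2, ] - box[1, ])

  probes <- .with_local_seed(seed, {
    for (k in seq_len(maxTries)) {
      p <- matrix(stats::runif(9, min = rep(box[1, ], each = 3),
                               max = rep(box[2, ], each = 3)),
                  nrow = 3, byrow = FALSE)
      vol <- abs(det(sweep(p, 2L, iso))) / 6
      if (vol >= minTetraVolume) break
      p <- NULL
    }
    p
  })
  if (is.null(probes))
    stop("could not draw non-coplanar probe points in ", maxTries, " tries")
  colnames(probes) <- c("x", "y", "z")

  points <- rbind(isocenter = iso, probe1 = probes[1, ],
                  probe2 = probes[2, ], probe3 = probes[3, ])
  bc <- matrix(NA_real_, nrow = length(levels), ncol = 4L,
               dimnames = list(paste0(levels, "%"),
                               c("isocenter", "probe1", "probe2", "probe3")))
  for (i in seq_along(levels)) {
    sr <- extractIsodoseSurface(ref, levels[i], source = "reference")
    se <- extractIsodoseSurface(eval, levels[i], source = "evaluated")
    for (j in 1:4) {
      pr <- distancesFromPoint(sr, points[j, ])
      pe <- distancesFromPoint(se, points[j, ])
      bc[i, j] <- brayCurtis(pairHistograms(pr, pe, level = levels[i]),
                             normalize = normalize)
    }
  }

  suspected <- any(bc[, 1] < epsilon &
                   apply(bc[, -1, drop = FALSE], 1L, max) > epsilon)
  new("RotationCheckResult", levelsChecked = as.numeric(levels),
      probePoints = probes, isocenter = iso, bcMatrix = bc,
      rotationSuspected = suspected, epsilon = epsilon, seed = seed)
}

## Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
## stream.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
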