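test_that("plan generation samples the analytic field deterministically", {
  g <- sphere20()  # linear falloff, r0 = 20, 45^3 grid, 1 mm spacing
  v <- doseValues(g)
  expect_equal(max(v), 2)  # dMax reproduced
  ## voxel at 10 mm from the center carries 50% of dMax
  center <- (dim(v) + 1) / 2
  expect_equal(v[center[1] + 10, center[2], center[3]], 1)
  expect_equal(v[center[1], center[2], center[3]], 2)
  ## determinism: same spec twice -> identical grids
  g2 <- makePlan(shape = "sphere", falloff = "linear", r0 = 20,
                 gridDim = rep(45, 3))
  expect_identical(doseValues(g), doseValues(g2))
})

test_that("analytic isodose radii match their closed forms and a bisection
           oracle", {
  sp <- planSpec(shape = "sphere", falloff = "linear", r0 = 100,
                 gridDim = rep(231, 3))
  expect_equal(analyticIsodoseRadius(sp, 95), 5)
  expect_equal(analyticIsodoseRadius(sp, 100), 0)
  expect_error(analyticIsodoseRadius(sp, 150), "\\(0, 100]")

  spq <- planSpec(shape = "sphere", falloff = "quadratic", r0 = 20,
                  gridDim = rep(45, 3))
  expect_equal(analyticIsodoseRadius(spq, 75), 10)

  ## sigmoid: radius equals an independent bisection root of the profile
  sps <- planSpec(shape = "sphere", falloff = "sigmoid", r0 = 40,
                  gridDim = rep(93, 3))
  prof <- function(s) {
    g <- function(u) 1 / (1 + exp((u - 20) / 2))
    g(s) / g(0)
  }
  for (lv in c(20, 50, 80)) {
    root <- uniroot(function(s) prof(s) - lv / 100, c(0, 90),
                    tol = 1e-10)$root
    expect_equal(analyticIsodoseRadius(sps, lv), root, tolerance = 1e-6)
  }
})

test_that("extracted equivalent radii track the analytic radius within a
           voxel", {
  sp <- planSpec(shape = "sphere", falloff = "linear", r0 = 20,
                 gridDim = rep(45, 3))
  rc <- buildRadiusCurve(sphere20_pct())
  lv <- seq(10, 95, 5)
  expect_lt(max(abs(rc@radii[lv] - analyticIsodoseRadius(sp, lv))), 1)
})

test_that("rigid shifts translate the field and compose to identity", {
  g <- sphere20()
  expect_identical(applyShift(g, c(0, 0, 0)), g)
  ## inverse composition restores the interior within interpolation error
  gg <- applyShift(applyShift(g, c(0, 0, 2)), c(0, 0, -2))
  interior <- doseValues(sphere20_pct()) > 10
  expect_lt(max(abs(doseValues(gg) - doseValues(g))[interior]), 0.02)
  ## isocenter metadata untouched; surface centroid displaced by the shift
  sh <- applyShift(g, c(2, 0, 0))
  expect_equal(isocenter(sh), isocenter(g))
  s <- extractIsodoseSurface(toPercent(sh), 50)
  expect_equal(unname(colMeans(surfacePoints(s))), c(2, 0, 0),
               tolerance = 0.3)
  expect_error(applyShift(g, c(30, 0, 0)), "excessive")
})

test_that("shifted-sphere distance samples span the analytic interval", {
  ## sphere radius R shifted by d: isocentric distances span [R - d, R + d]
  g <- sphere20()
  d <- 3
  sh <- applyShift(g, c(0, 0, d))
  dist <- distancesFromPoint(extractIsodoseSurface(toPercent(sh), 50),
                             isocenter(g))
  R <- 10  # 50% isodose of the linear falloff
  tol <- sqrt(3)  # one voxel diagonal
  expect_lt(abs(min(dist) - (R - d)), tol)
  expect_lt(abs(max(dist) - (R + d)), tol)
  expect_lt(abs(median(as.numeric(dist)) - sqrt(R^2 + d^2)), tol)
})

test_that("the two-lobe plan exposes both dose maxima", {
  g <- makePlan(shape = "twolobe", falloff = "linear", r0 = 20,
                lobeOffset = 24, lobeFraction = 0.8, gridDim = rep(71, 3))
  v <- doseValues(g)
  c0 <- (dim(v) + 1) / 2
  expect_equal(v[c0[1] - 12, c0[2], c0[3]], 2)        # primary lobe center
  expect_equal(v[c0[1] + 12, c0[2], c0[3]], 1.6)      # secondary lobe
  ## radius curve still satisfies its monotone invariants
  rc <- buildRadiusCurve(toPercent(g))
  expect_true(all(diff(rc@radii) <= 1e-12))
  ## the secondary prescription level leaves a signature: the enclosed
  ## volume drops sharply when the 80% lobe falls out
  vols <- rc@volumes
  jump <- vols[78] / vols[82]
  expect_gt(jump, 1.5)
})

test_that("plan specs validate and round-trip through JSON", {
  expect_error(planSpec(r0 = -1), "positive")
  expect_error(planSpec(r0 = 100, gridDim = rep(45, 3)), "incompatible")
  sp <- planSpec(shape = "ellipsoid", falloff = "sigmoid", r0 = 30,
                 axes = c(1, 0.8, 0.6), orientation = 12.5)
  f <- tempfile(fileext = ".json")
  writePlanSpec(sp, f)
  expect_equal(readPlanSpec(f), sp)
})

test_that("analytic rotation of the generated field matches resampled
           rotation in the interior", {
  a <- makePlan(shape = "ellipsoid", falloff = "sigmoid", r0 = 20,
                axes = c(1, 0.7, 0.85), gridDim = rep(47, 3))
  rot_exact <- makePlan(shape = "ellipsoid", falloff = "sigmoid", r0 = 20,
                        axes = c(1, 0.7, 0.85), orientation = 25,
                        gridDim = rep(47, 3))
  rot_res <- applyRotation(a, 25, "z")
  interior <- doseValues(toPercent(a)) > 15
  expect_lt(max(abs(doseValues(rot_res) -
                    doseValues(rot_exact))[interior]) / 2, 0.01)
})
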