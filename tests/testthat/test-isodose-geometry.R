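test_that("extracted isodose points lie on the analytic isosurface", {
  p <- sphere20_pct()  # D(r) = 100 (1 - r/20): level x at radius 20(1-x/100)
  voxel_diag <- sqrt(sum(gridSpacing(p)^2))
  for (lv in c(25, 50, 75)) {
    s <- extractIsodoseSurface(p, lv)
    d <- distancesFromPoint(s, c(0, 0, 0))
    r_true <- 20 * (1 - lv / 100)
    expect_lt(max(abs(d - r_true)), voxel_diag)
  }
})

test_that("missing and degenerate isodoses are rejected by level", {
  p <- sphere20_pct()
  expect_error(extractIsodoseSurface(p, 150), "missing isodose")
  expect_error(extractIsodoseSurface(p, -5), "positive")
  ## level exactly at a single maximal voxel: either a tiny (<= 8 point)
  ## degenerate surface or a missing-isodose error
  res <- tryCatch(extractIsodoseSurface(p, 100), error = function(e) e)
  if (inherits(res, "error")) expect_match(conditionMessage(res), "missing")
  else expect_lte(nrow(surfacePoints(res)), 8)
})

test_that("voxel-shell extraction is available as a config option", {
  p <- sphere20_pct()
  s <- extractIsodoseSurface(p, 50, method = "voxel")
  d <- distancesFromPoint(s, c(0, 0, 0))
  expect_lt(max(abs(d - 10)), sqrt(3))  # shell voxels within one diagonal
})

test_that("distances from a point follow Euclid and are equivariant", {
  s <- new("IsodoseSurface", level = 50,
           points = rbind(c(3, 4, 0), c(0, 0, 0), c(1, 2, 2)),
           source = "unspecified")
  expect_equal(as.numeric(distancesFromPoint(s, c(0, 0, 0))), c(5, 0, 3))
  ## translation equivariance
  t <- c(-7, 11, 0.5)
  s2 <- new("IsodoseSurface", level = 50,
            points = sweep(s@points, 2, t, "+"), source = "unspecified")
  expect_equal(as.numeric(distancesFromPoint(s2, t)),
               as.numeric(distancesFromPoint(s, c(0, 0, 0))))
})

test_that("enclosed volume counts voxels and matches the analytic ball", {
  u <- PercentDoseGrid(array(100, c(10, 10, 10)))
  expect_equal(enclosedVolume(u, 50), 1000)
  expect_equal(enclosedVolume(u, 100.5), 0)

  p <- sphere20_pct()
  for (lv in c(30, 50, 70)) {
    r <- 20 * (1 - lv / 100)
    v_true <- 4 / 3 * pi * r^3
    shell <- 4 * pi * r^2 * sqrt(3)  # one voxel-diagonal shell
    expect_lt(abs(enclosedVolume(p, lv) - v_true), shell)
  }
})

test_that("equivalent radius inverts the sphere volume", {
  expect_equal(equivalentRadius(4 * pi / 3), 1)
  expect_equal(equivalentRadius(0), 0)
  expect_equal(equivalentRadius(113.097), 3, tolerance = 1e-4)
  expect_error(equivalentRadius(-1), "non-negative")
})

test_that("radius curve is monotone and tracks the analytic gradient", {
  p <- sphere20_pct()
  rc <- buildRadiusCurve(p)
  df <- as.data.frame(rc)
  expect_equal(df$level, 1:100)
  expect_true(all(diff(df$volume) <= 0))
  expect_true(all(diff(df$radius) <= 1e-12))
  expect_true(all(df$radiusDiff >= 0, na.rm = TRUE))
  ## linear falloff: dr/dx = r0/100 = 0.2 mm per % at mid levels; single
  ## levels carry voxelization noise, the running mean does not
  expect_lt(abs(mean(df$radiusDiff[df$level %in% 20:80]) - 0.2), 0.02)
  expect_lt(max(abs(df$radiusDiff[df$level %in% 20:60] - 0.2)), 0.15)

  ## uniform grid: radii constant, diffs ~ 0
  u <- PercentDoseGrid(array(100, c(10, 10, 10)))
  rcu <- buildRadiusCurve(u)
  expect_equal(max(rcu@radiusDiffs, na.rm = TRUE), 0)

  ## quadratic falloff: gradient shallow at high levels -> larger diffs there
  q <- toPercent(makePlan(shape = "sphere", falloff = "quadratic", r0 = 20,
                          gridDim = rep(45, 3)))
  dq <- as.data.frame(buildRadiusCurve(q))$radiusDiff
  expect_gt(mean(dq[85:95]), mean(dq[20:30]))
  ## and the profile follows dr/dx of the analytic inverse at mid levels
  x <- 30:90
  analytic <- 20 * (sqrt(1 - (x - 1) / 100) - sqrt(1 - x / 100))
  expect_gt(cor(dq[x], analytic), 0.8)
})
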