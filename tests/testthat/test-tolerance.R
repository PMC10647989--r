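## Helper: a synthetic RadiusCurve with prescribed radius differences.
curve_from_diffs <- function(levels, diffs, r_start = 120) {
  radii <- r_start - cumsum(c(0, diffs[-1]))
  new("RadiusCurve", levels = as.numeric(levels),
      volumes = 4 / 3 * pi * radii^3, radii = radii,
      radiusDiffs = as.numeric(diffs))
}

test_that("ISOmr sits at the midrange of the radius differences", {
  ## linearly rising differences 0.1 -> 0.9 over levels 1..100
  diffs <- c(NA, 0.1 + 0.8 * (2:100 - 1) / 99)
  rc <- curve_from_diffs(1:100, diffs)
  ## independent brute-force scan with the tie rule
  d <- diffs[-1]
  m <- (max(d) + min(d)) / 2
  dev <- abs(d - m)
  expected <- max((2:100)[dev <= min(dev) + 1e-12])
  got <- selectIsoMr(rc)
  expect_equal(got, expected)
  expect_true(abs(got - 50.5) <= 1)

  ## explicit tie breaks toward the higher level
  rc2 <- new("RadiusCurve", levels = c(50, 51), volumes = c(100, 50),
             radii = c(10, 7), radiusDiffs = c(1, 3))
  expect_equal(selectIsoMr(rc2), 51)

  ## flat curve: no gradient structure
  rcf <- curve_from_diffs(1:100, c(NA, rep(0.3, 99)))
  expect_error(selectIsoMr(rcf), "no gradient structure")

  ## override passes through
  expect_equal(selectIsoMr(rc, override = 80), 80)
  expect_error(selectIsoMr(rc, override = 350), "curve levels")
})

test_that("ISOmr from a sigmoid plan equals an independent argmin scan", {
  rc <- buildRadiusCurve(ellipsoid30_pct())
  df <- as.data.frame(rc)
  ok <- is.finite(df$radiusDiff)
  m <- (max(df$radiusDiff[ok]) + min(df$radiusDiff[ok])) / 2
  dev <- abs(df$radiusDiff - m)
  expected <- max(df$level[ok][dev[ok] <= min(dev[ok]) + 1e-12])
  expect_equal(selectIsoMr(rc), expected)
})

test_that("the 1 mm criterion inverts the analytic radius-level curve", {
  ## r(x) = 100 - x  ->  +/- 1 mm maps to +/- 1 percentage point
  rc <- new("RadiusCurve", levels = 1:100, volumes = rep(1, 100),
            radii = 100 - (1:100),
            radiusDiffs = c(NA, rep(1, 99)))
  iv <- deriveDoseInterval(rc, 50, 1.0)
  expect_equal(iv$deltaUp, 1.0)
  expect_equal(iv$deltaLow, 1.0)

  ## r(x) = 50 - x/2  ->  2 percentage points
  rc2 <- new("RadiusCurve", levels = 1:100, volumes = rep(1, 100),
             radii = 50 - (1:100) / 2,
             radiusDiffs = c(NA, rep(0.5, 99)))
  iv2 <- deriveDoseInterval(rc2, 50, 1.0)
  expect_equal(iv2$deltaUp, 2.0)
  expect_equal(iv2$deltaLow, 2.0)

  ## zero tolerance degenerates to zero offsets
  iv0 <- deriveDoseInterval(rc, 50, 0)
  expect_equal(iv0$deltaUp, 0)
  expect_equal(iv0$deltaLow, 0)

  ## ranges too small to move 1 mm error with the direction named
  expect_error(deriveDoseInterval(rc, 99, 1.5), "higher")
  expect_error(deriveDoseInterval(rc, 1, 1.5), "lower")
})

test_that("tolerance band: reference-only limits with the expected geometry", {
  band <- sphere25_band()
  lim <- as.data.frame(band)
  av <- lim[lim$available, ]
  expect_gt(nrow(av), 10)
  expect_true(all(av$bcUp > 0 & av$bcLow > 0))

  ## ISOup is always closer to the isocenter: r(levelUp) < r(level)
  rc <- buildRadiusCurve(sphere25_pct())
  r <- rc@radii
  expect_true(all(r[av$levelUp] < r[av$level]))

  ## mirror symmetry of a centered linear radial field: upper and lower
  ## limits coincide at mid levels
  bsym <- suppressWarnings(
    buildToleranceBand(sphere20_pct(), levels = seq(30, 70, 10)))
  lsym <- as.data.frame(bsym)
  expect_lt(max(abs(lsym$bcUp - lsym$bcLow) /
                pmax(lsym$bcUp, lsym$bcLow)), 0.1)

  ## spatial-tolerance monotonicity: wider criterion, never smaller limits
  band2 <- suppressWarnings(
    buildToleranceBand(sphere25_pct(), levels = seq(20, 80, 10),
                       spatialTol = 2))
  lim2 <- as.data.frame(band2)
  joint <- merge(av, lim2[lim2$available, ], by = "level")
  expect_true(all(joint$bcUp.y >= joint$bcUp.x - 1e-9))
  expect_true(all(joint$bcLow.y >= joint$bcLow.x - 1e-9))

  ## degenerate zero interval is rejected outright
  expect_error(buildToleranceBand(sphere25_pct(), spatialTol = 0),
               "degenerate|non-negative")
})

test_that("unavailable levels are dropped with a warning, never defaulted", {
  ## level 100 + a positive offset always exceeds the range
  expect_warning(
    b <- buildToleranceBand(sphere25_pct(), levels = c(40, 60, 100)),
    "unavailable")
  lim <- as.data.frame(b)
  expect_false(lim$available[lim$level == 100])
  expect_true(all(is.na(lim[lim$level == 100, c("bcLow", "bcUp")])))
})
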