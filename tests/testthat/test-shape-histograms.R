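test_that("Doane bin count follows the formula", {
  ## n = 1024 exactly symmetric: skew term vanishes -> ceil(1 + 10 + 0) = 11
  x <- rep(c(4, 6), 512)
  expect_equal(doaneBinCount(x), 11L)

  ## zero-variance sample: single degenerate bin
  k <- doaneBinCount(rep(5, 100))
  expect_equal(as.integer(k), 1L)
  expect_true(attr(k, "degenerate"))

  expect_error(doaneBinCount(c(1, 2, 3)), "at least 4")

  ## skewed sample: matches an independent evaluation of the formula with
  ## e1071's adjusted Fisher-Pearson skewness (type 2)
  skip_if_not_installed("e1071")
  set.seed(99)
  d <- rexp(500, rate = 0.5)
  g1 <- e1071::skewness(d, type = 2)
  sigma <- sqrt(6 * (500 - 2) / ((500 + 1) * (500 + 3)))
  expected <- max(4L, as.integer(ceiling(1 + log2(500) +
                                         log2(1 + abs(g1) / sigma))))
  expect_equal(doaneBinCount(d), expected)
})

test_that("shape histograms bin correctly and keep the raw median", {
  h <- buildShapeHistogram(c(1, 1, 3, 3), edges = c(0, 2, 4))
  expect_equal(binCounts(h), c(2, 2))
  expect_equal(medianDistance(h), 2)

  ## all points on a sphere radius R: single occupied bin containing R
  h2 <- buildShapeHistogram(rep(12.5, 50))
  expect_equal(sum(binCounts(h2) > 0), 1L)
  expect_equal(medianDistance(h2), 12.5)
  expect_true(h2@degenerate)

  ## conservation for arbitrary samples
  set.seed(1)
  for (n in c(10, 200, 4321)) {
    d <- rgamma(n, shape = 3, scale = 5)
    expect_equal(sum(binCounts(buildShapeHistogram(d))), n)
  }

  expect_error(buildShapeHistogram(numeric()), "empty")
  expect_error(buildShapeHistogram(c(1, 2, 3, 4), edges = c(2, 1)),
               "ascending")
})

test_that("histogram pairs share reference-anchored edges over the union", {
  set.seed(2)
  r <- rnorm(500, 30, 2)
  pair <- pairHistograms(r, r)
  expect_identical(binCounts(pair@reference), binCounts(pair@evaluated))

  ## shifted sample: mass moves right, counts conserved, edges span union
  e <- r + 1
  pair2 <- pairHistograms(r, e)
  expect_equal(sum(binCounts(pair2@reference)), 500)
  expect_equal(sum(binCounts(pair2@evaluated)), 500)
  expect_gte(min(binEdges(pair2@reference)), min(r, e) - 1e-9)
  expect_lte(max(r, e), max(binEdges(pair2@reference)) + 1e-9)
  wmean <- function(h) {
    mids <- (binEdges(h)[-1] + head(binEdges(h), -1)) / 2
    sum(mids * binCounts(h)) / sum(binCounts(h))
  }
  expect_gt(wmean(pair2@evaluated), wmean(pair2@reference))

  ## disjoint ranges are handled without error
  pair3 <- pairHistograms(rnorm(100, 10, 0.5), rnorm(100, 40, 0.5))
  expect_equal(sum(binCounts(pair3@reference)), 100)
})

test_that("Bray-Curtis hits its endpoints and is a bounded symmetric index", {
  ## identical histograms: perfect match
  expect_equal(brayCurtis(c(3, 2, 1), c(3, 2, 1)), 0)
  ## disjoint support: maximal dissimilarity
  expect_equal(brayCurtis(c(0, 0, 5), c(4, 1, 0)), 1)
  ## direct evaluation on raw counts
  expect_equal(brayCurtis(c(2, 1, 0), c(0, 1, 2), normalize = FALSE), 2 / 3,
               tolerance = 1e-12)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(1, 2), c(1, 2, 3)), "identical edges")

  set.seed(3)
  for (i in 1:20) {
    a <- rpois(8, 5)
    b <- rpois(8, 5)
    if (sum(a) == 0 || sum(b) == 0) next
    bc <- brayCurtis(a, b)
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    expect_equal(bc, brayCurtis(b, a))
    ## sample-size invariance under normalization
    expect_equal(brayCurtis(2 * a, b), bc)
  }
})

test_that("Bray-Curtis matches vegan on raw counts", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:10) {
    a <- rpois(12, 4) + c(rep(0, 6), rep(3, 6))
    b <- rpois(12, 4)
    expect_equal(brayCurtis(a, b, normalize = FALSE),
                 as.numeric(vegan::vegdist(rbind(a, b), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("radial expansion raises the median distance (sign basis)", {
  p <- sphere25_pct()
  d <- distancesFromPoint(extractIsodoseSurface(p, 50), isocenter(p))
  expect_gt(median(as.numeric(d) + 1.5), median(as.numeric(d)))
  ## hotter plan: same isodose sits at larger radius -> larger median
  hot <- new("PercentDoseGrid", values = pmin(doseValues(p) + 4, 100),
             spacing = gridSpacing(p), origin = gridOrigin(p),
             isocenter = isocenter(p))
  dh <- distancesFromPoint(extractIsodoseSurface(hot, 50), isocenter(p))
  expect_gt(median(as.numeric(dh)), median(as.numeric(d)))
})
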