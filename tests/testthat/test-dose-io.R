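test_that("dose grid construction enforces invariants", {
  v <- array(0, c(3, 3, 3))
  v[2, 2, 2] <- 2
  g <- DoseGrid(v, spacing = c(1, 1, 1))
  expect_equal(doseMax(g), 2)
  expect_error(DoseGrid(array(-1, c(3, 3, 3))), "non-negative")
  expect_error(DoseGrid(v, spacing = c(1, 0, 1)), "strictly positive")
  expect_warning(DoseGrid(v, isocenter = c(50, 0, 0)), "outside")
})

test_that("plain container round-trips a grid to representation precision", {
  set.seed(42)
  g <- DoseGrid(array(runif(27, 0, 2), c(3, 3, 3)),
                spacing = c(1, 2, 2.5), origin = c(-1, -2, -2.5),
                isocenter = c(0.25, 0, 0))
  f <- tempfile(fileext = ".dose.json")
  writeDoseGrid(g, f)
  g2 <- readDoseGrid(f)
  expect_s4_class(g2, "DoseGrid")
  expect_equal(doseValues(g2), doseValues(g), tolerance = 1e-12)
  expect_equal(gridSpacing(g2), gridSpacing(g))
  expect_equal(gridOrigin(g2), gridOrigin(g))
  expect_equal(isocenter(g2), isocenter(g))

  ## percent grids keep their class through the container
  p <- toPercent(g)
  writeDoseGrid(p, f)
  expect_s4_class(readDoseGrid(f), "PercentDoseGrid")

  expect_error(readDoseGrid(tempfile()), "not found")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), bad)
  expect_error(readDoseGrid(bad), "not an isodiff dose container")
})

test_that("percent conversion normalizes, preserves order, and validates", {
  g <- DoseGrid(array(2, c(4, 4, 4)))
  expect_true(all(doseValues(toPercent(g)) == 100))

  v <- array(seq(0, 2, length.out = 64), c(4, 4, 4))
  v[2, 1, 1] <- 1
  g <- DoseGrid(v)
  p <- toPercent(g)
  expect_equal(max(doseValues(p)), 100)
  expect_equal(doseValues(p)[2, 1, 1], 50)
  ## monotone, order-preserving over voxels
  expect_equal(order(doseValues(p)), order(v))

  p80 <- toPercent(g, "explicit_dose", dose = 2.5)
  expect_equal(doseValues(p80)[v == 2], 80)
  expect_error(toPercent(g, "explicit_dose", dose = 0), "positive")
  expect_error(toPercent(DoseGrid(array(0, c(3, 3, 3)))), "not positive")
})

test_that("DICOM RTDOSE written by pydicom is read back correctly", {
  set.seed(7)
  vals <- array(runif(5 * 4 * 3, 0, 2), c(5, 4, 3))
  scaling <- 1e-4
  vals <- round(vals / scaling) * scaling  # exactly representable
  for (cfgs in list(list(bits = 32L, implicit = FALSE),
                    list(bits = 32L, implicit = TRUE),
                    list(bits = 16L, implicit = FALSE))) {
    f <- tempfile(fileext = ".dcm")
    write_rtdose_py(vals, spacing = c(1, 2, 2.5), origin = c(-2, -3, -2.5),
                    scaling = scaling, path = f, bits = cfgs$bits,
                    implicit = cfgs$implicit)
    g <- readDicomDose(f)
    expect_equal(doseValues(g), vals, tolerance = 1e-9)
    expect_equal(gridSpacing(g), c(1, 2, 2.5))
    expect_equal(gridOrigin(g), c(-2, -3, -2.5))
  }
})

test_that("loadDoseGrid dispatches on content and handles the isocenter", {
  vals <- array(seq(0, 1, length.out = 27), c(3, 3, 3))
  f <- tempfile(fileext = ".dcm")
  write_rtdose_py(vals, spacing = c(1, 1, 1), origin = c(-1, -1, -1),
                  scaling = 1e-5, path = f)
  expect_error(loadDoseGrid(f), "isocenterOverride")
  g <- loadDoseGrid(f, isocenterOverride = c(0, 0, 0))
  expect_equal(isocenter(g), c(0, 0, 0))

  fc <- tempfile(fileext = ".dose.json")
  writeDoseGrid(DoseGrid(vals), fc)
  g2 <- loadDoseGrid(fc, isocenterOverride = c(0.5, 0, 0))
  expect_equal(isocenter(g2), c(0.5, 0, 0))
  expect_error(loadDoseGrid(fc, isocenterOverride = 1:2), "length 3")
})

test_that("DICOM reader rejects what it cannot interpret", {
  vals <- array(1, c(3, 3, 3))
  f <- tempfile(fileext = ".dcm")
  write_rtdose_py(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                  scaling = 1e-3, path = f, modality = "CT")
  expect_error(readDicomDose(f), "Modality")
  junk <- tempfile()
  writeBin(as.raw(rep(0, 200)), junk)
  expect_error(readDicomDose(junk), "DICM")
})
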