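makeResult <- function(amplitude, width = c(20, 7, 6, 5, 25),
                       grid = fixtureGrid(), offset = 0.35,
                       partition = 0.98) {
  comps <- data.frame(center = sort(unname(peakCenters)),
                      amplitude = amplitude, width = width,
                      fwhm = 2 * sqrt(2 * log(2)) * width,
                      at_bound = FALSE)
  y <- evalCumulative(comps, offset, grid)
  new("DeconvolutionResult", wavelength = grid, observed = y,
      components = comps, offset = offset, fitted = y,
      residuals = rep(0, length(grid)), mse = 0, tolerance = 0.02,
      residualFraction = 1.0, partition = partition, accepted = TRUE,
      convergence = list())
}

test_that("indices combine component areas as defined", {
  g <- fixtureGrid()
  # equal areas a for all five components -> hb = 2a, bili = a, spo2 = 1
  a <- 2.5
  centers <- sort(unname(peakCenters))
  widths <- c(20, 7, 6, 5, 25)
  amps <- vapply(1:5, function(i)
    a / componentAUC(centers[i], 1, widths[i], g), 0)
  idx <- computeIndices(makeResult(amps, widths))
  expect_equal(idx@hb, 2 * a, tolerance = 1e-12)
  expect_equal(idx@bilirubin, a, tolerance = 1e-12)
  expect_equal(idx@spo2, 1.0, tolerance = 1e-12)

  # zero bilirubin amplitude -> zero bilirubin index
  idx0 <- computeIndices(makeResult(c(0, amps[-1]), widths))
  expect_equal(idx0@bilirubin, 0)

  # indices equal hand-summed component AUCs
  set.seed(11)
  amps2 <- runif(5, 0.05, 0.4)
  res <- makeResult(amps2, widths)
  idx2 <- computeIndices(res)
  auc <- vapply(1:5, function(i)
    componentAUC(centers[i], amps2[i], widths[i], g), 0)
  expect_lt(abs(idx2@hb - (auc[2] + auc[4])), 1e-12)
  expect_lt(abs(idx2@bilirubin - auc[1]), 1e-12)
  expect_lt(abs(idx2@spo2 - auc[4] / auc[3]), 1e-12)
})

test_that("the 620 nm baseline component never leaks into indices", {
  widths <- c(20, 7, 6, 5, 25)
  set.seed(12)
  amps <- runif(5, 0.05, 0.4)
  base <- computeIndices(makeResult(amps, widths))
  for (a620 in c(0, 0.2, 1.5)) {
    amps2 <- amps; amps2[5] <- a620
    idx <- computeIndices(makeResult(amps2, widths))
    expect_equal(idx@hb, base@hb, tolerance = 1e-12)
    expect_equal(idx@bilirubin, base@bilirubin, tolerance = 1e-12)
    expect_equal(idx@spo2, base@spo2, tolerance = 1e-12)
  }
})

test_that("rejected fits refuse index computation unless forced", {
  res <- makeResult(c(0.1, 0.2, 0.1, 0.2, 0.1))
  res@residualFraction <- 0.9
  res@accepted <- FALSE
  expect_error(computeIndices(res), "rejected")
  expect_s4_class(computeIndices(res, force = TRUE), "InstrumentIndices")

  zero_deoxy <- makeResult(c(0.1, 0.2, 0, 0.2, 0.1))
  expect_error(computeIndices(zero_deoxy), "degenerate")
})

test_that("calibration fits recover generating polynomials", {
  set.seed(13)
  x <- runif(30, 1, 10)
  # linear Hb: value = 1.8 * index + 2.91
  hb <- fitCalibration(pairedTable(x, 1.8 * x + 2.91), "Hb")
  expect_equal(hb@coefficients, c(2.91, 1.8), tolerance = 1e-9)
  expect_equal(hb@diagnostics$r, 1.0, tolerance = 1e-9)
  expect_identical(hb@family, "linear")

  # quadratic TSB from a known polynomial
  tsb_true <- c(0.3, 1.2, 0.07)
  y <- tsb_true[1] + tsb_true[2] * x + tsb_true[3] * x^2
  tsb <- suppressWarnings(fitCalibration(pairedTable(x, y), "TSB"))
  expect_lt(max(abs(tsb@coefficients - tsb_true) / abs(tsb_true)), 1e-6)
  expect_equal(tsb@diagnostics$adj_r_squared, 1.0, tolerance = 1e-9)

  # quartic SpO2 needs degree + 2 = 6 points
  expect_error(fitCalibration(pairedTable(1:4, 1:4), "SpO2"),
               "at least 6 rows")
  expect_error(fitCalibration(pairedTable(rep(2, 10), 1:10), "Hb"),
               "degenerate")
})

test_that("calibration application evaluates, flags and clamps", {
  idx <- new("InstrumentIndices", hb = 5, bilirubin = 4, spo2 = 1.2)
  models <- list(
    Hb = CalibrationModel("Hb", c(0, 1), indexRange = c(0, 10)),
    TSB = CalibrationModel("TSB", c(0, 1, 0), indexRange = c(0, 10)),
    SpO2 = CalibrationModel("SpO2", c(0, 1, 0, 0, 0),
                            indexRange = c(0, 3)))
  panel <- applyCalibration(idx, models)
  expect_equal(panel@hb, 5)      # identity-like linear model
  expect_equal(panel@tsb, 4)
  expect_equal(panel@spo2, 1.2)
  expect_false(panel@flags$spo2_clamped)
  expect_length(panel@flags$extrapolated, 0)

  # polynomial exceeding 100% is clamped and flagged
  models$SpO2 <- CalibrationModel("SpO2", c(103, 0, 0, 0, 0),
                                  indexRange = c(0, 3))
  panel2 <- applyCalibration(idx, models)
  expect_equal(panel2@spo2, 100)
  expect_true(panel2@flags$spo2_clamped)

  # index outside the model range flags extrapolation
  models$Hb <- CalibrationModel("Hb", c(0, 1), indexRange = c(6, 10))
  expect_true("Hb" %in% applyCalibration(idx, models)@flags$extrapolated)

  expect_error(applyCalibration(idx, models[c("Hb", "TSB")]), "SpO2")
})

test_that("calibration roundtrip through the generator inverse is exact", {
  models <- truthCalibration()
  for (val in list(c(10.2, 29.8, 92), c(19.1, 2.4, 95), c(7, 15, 75))) {
    idx <- new("InstrumentIndices",
               hb = invertCalibration(models$Hb, val[1]),
               bilirubin = invertCalibration(models$TSB, val[2]),
               spo2 = invertCalibration(models$SpO2, val[3]))
    panel <- applyCalibration(idx, models)
    expect_equal(c(panel@hb, panel@tsb, panel@spo2), val,
                 tolerance = 1e-6)
  }
})

test_that("calibration JSON files round-trip", {
  models <- truthCalibration()
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibration(models, path)
  back <- readCalibration(path)
  expect_setequal(names(back), c("Hb", "TSB", "SpO2"))
  for (a in names(models)) {
    expect_equal(back[[a]]@coefficients, models[[a]]@coefficients)
    expect_equal(back[[a]]@indexRange, models[[a]]@indexRange)
    expect_identical(back[[a]]@family, models[[a]]@family)
  }
})

test_that("classification applies the disease thresholds", {
  # anemic, jaundiced, hypoxic reference subject
  c1 <- classifyPanel(BloodPanel(hb = 10.2, tsb = 29.8, spo2 = 92))
  expect_true(c1@anemia)
  expect_false(c1@hypoxia)  # strict <: 92 is not hypoxic
  expect_true(c1@jaundice)

  # control subject: all flags clear
  c2 <- classifyPanel(BloodPanel(hb = 19.1, tsb = 2.4, spo2 = 95))
  expect_false(c2@anemia || c2@hypoxia || c2@jaundice)

  # boundary conventions: strict < for anemia/hypoxia, >= for jaundice
  expect_false(classifyPanel(BloodPanel(11, 0, 98))@anemia)
  expect_true(classifyPanel(BloodPanel(10.99, 0, 98))@anemia)
  expect_true(classifyPanel(BloodPanel(15, 0, 91.9))@hypoxia)
  expect_true(classifyPanel(BloodPanel(15, 15, 98))@jaundice)
  expect_false(classifyPanel(BloodPanel(15, 14.99, 98))@jaundice)
})

test_that("classification is monotone in each analyte", {
  thr <- hemospecConfig()$classify
  hb_flags <- vapply(seq(5, 22, length.out = 30), function(h)
    classifyPanel(BloodPanel(h, 5, 98), thr)@anemia, TRUE)
  expect_true(all(diff(as.integer(hb_flags)) <= 0))
  spo2_flags <- vapply(seq(60, 100, length.out = 30), function(s)
    classifyPanel(BloodPanel(15, 5, s), thr)@hypoxia, TRUE)
  expect_true(all(diff(as.integer(spo2_flags)) <= 0))
  tsb_flags <- vapply(seq(0, 30, length.out = 30), function(t)
    classifyPanel(BloodPanel(15, t, 98), thr)@jaundice, TRUE)
  expect_true(all(diff(as.integer(tsb_flags)) >= 0))
})
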