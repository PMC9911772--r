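test_that("boxcar smoothing matches a naive windowed-mean loop", {
  w <- seq(450, 470, by = 0.5)
  set.seed(3)
  y <- runif(length(w))
  spec <- RawSpectrum(w, y, "sample")

  naive <- function(y, width) {
    n <- length(y)
    vapply(seq_len(n), function(i) {
      h <- min(width, i - 1L, n - i)
      mean(y[(i - h):(i + h)])
    }, 0)
  }
  for (width in c(0L, 1L, 2L, 5L))
    expect_equal(intensities(boxcarSmooth(spec, width)), naive(y, width))

  # width 0 is the identity; constants are fixed points
  expect_identical(intensities(boxcarSmooth(spec, 0L)), y)
  const <- RawSpectrum(w, rep(7, length(w)), "dark")
  expect_equal(intensities(boxcarSmooth(const, 3L)), rep(7, length(w)))

  # linear ramp: interior unchanged, edges are truncated-window means
  ramp <- RawSpectrum(w, seq_along(w), "sample")
  sm <- intensities(boxcarSmooth(ramp, 2L))
  expect_equal(sm[3:(length(w) - 2)], seq_along(w)[3:(length(w) - 2)])
  expect_equal(sm[1], 1)        # 1-point truncated window
  expect_equal(sm[2], mean(1:3))
})

test_that("boxcar smoothing never extends the value range", {
  set.seed(4)
  for (i in 1:10) {
    y <- rnorm(50)
    sm <- intensities(boxcarSmooth(RawSpectrum(seq(450, 499, 1), pmax(y, 0),
                                               "sample"), 3L))
    expect_gte(min(sm), min(pmax(y, 0)))
    expect_lte(max(sm), max(pmax(y, 0)))
  }
  expect_error(boxcarSmooth(RawSpectrum(c(450, 451), c(1, 1)), 1L),
               "too short")
  expect_error(boxcarSmooth(RawSpectrum(c(450, 451), c(1, 1)), -1L),
               "non-negative")
})

test_that("absorbance follows the dark-corrected log ratio", {
  w <- fixtureGrid()
  n <- length(w)
  ref <- RawSpectrum(w, rep(10000, n), "reference")
  dark <- RawSpectrum(w, rep(0, n), "dark")

  # sample == reference: zero absorbance everywhere
  a0 <- computeAbsorbance(RawSpectrum(w, rep(10000, n), "sample"), dark, ref)
  expect_equal(absorbance(a0), rep(0, n))

  # 10% transmitted: absorbance exactly 1
  a1 <- computeAbsorbance(RawSpectrum(w, rep(1000, n), "sample"), dark, ref)
  expect_equal(absorbance(a1), rep(1, n))

  # random positive triple vs independently coded scalar evaluation
  set.seed(5)
  d <- runif(n, 100, 500)
  r <- d + runif(n, 5000, 9000)
  s <- d + (r - d) * runif(n, 0.05, 0.95)
  out <- computeAbsorbance(RawSpectrum(w, s, "sample"),
                           RawSpectrum(w, d, "dark"),
                           RawSpectrum(w, r, "reference"))
  idx <- sample(n, 20)
  for (i in idx) {
    scalar <- -log10((s[i] - d[i]) / (r[i] - d[i]))
    expect_lt(abs(absorbance(out)[i] - scalar), 1e-12)
  }
})

test_that("absorbance is invariant under offset shifts preserving both differences", {
  w <- seq(450, 650, by = 1)
  n <- length(w)
  set.seed(6)
  d <- runif(n, 100, 200)
  r <- d + runif(n, 4000, 6000)
  s <- d + (r - d) * runif(n, 0.2, 0.8)
  base <- absorbance(computeAbsorbance(RawSpectrum(w, s, "sample"),
                                       RawSpectrum(w, d, "dark"),
                                       RawSpectrum(w, r, "reference")))
  shift <- 321.5
  shifted <- absorbance(computeAbsorbance(
    RawSpectrum(w, s + shift, "sample"), RawSpectrum(w, d + shift, "dark"),
    RawSpectrum(w, r + shift, "reference")))
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("absorbance reports acquisition faults with wavelengths", {
  w <- c(450, 451, 452)
  s <- RawSpectrum(w, c(100, 100, 100), "sample")
  d <- RawSpectrum(w, c(50, 50, 50), "dark")
  r_bad <- RawSpectrum(w, c(200, 50, 200), "reference")
  expect_error(computeAbsorbance(s, d, r_bad), "reference - dark.*451",
               fixed = FALSE)
  s_bad <- RawSpectrum(w, c(100, 50, 100), "sample")
  r <- RawSpectrum(w, c(200, 200, 200), "reference")
  expect_error(computeAbsorbance(s_bad, d, r), "sample - dark.*451",
               fixed = FALSE)
  s2 <- RawSpectrum(w + 1, c(100, 100, 100), "sample")
  expect_error(computeAbsorbance(s2, d, r), "share a wavelength grid")
})

test_that("620 nm gate applies the inclusive interval", {
  w <- fixtureGrid()  # 620 falls between grid points
  cases <- data.frame(level = c(0.49, 0.50, 0.55, 0.60, 0.61),
                      pass = c(FALSE, TRUE, TRUE, TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    gate <- checkGate(AbsorbanceSpectrum(w, rep(cases$level[i], length(w))))
    expect_identical(gate@passed, cases$pass[i])
    expect_identical(isAccepted(gate), cases$pass[i])
    expect_equal(gate@value, cases$level[i])
  }
})

test_that("gate interpolates linearly between flanking grid points", {
  w <- c(619, 621)
  sp <- AbsorbanceSpectrum(w, c(0.5, 0.6))
  gate <- checkGate(sp)
  expect_equal(gate@value, 0.55)  # midpoint of a linear segment
  expect_true(gate@passed)

  expect_error(checkGate(AbsorbanceSpectrum(c(450, 500), c(1, 1))),
               "cover")
})
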