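test_that("cumulative model matches an independent per-Gaussian scalar sum", {
  g <- fixtureGrid()
  comps <- fixtureComponents()

  expect_equal(evalCumulative(transform(comps, amplitude = 0), 0.3, g),
               rep(0.3, length(g)))

  one <- transform(comps, amplitude = c(0, 0.4, 0, 0, 0))
  at_center <- evalCumulative(one, 0.1, comps$center[2])
  expect_equal(at_center, 0.5)  # y0 + A at the component's own center

  set.seed(7)
  comps$amplitude <- runif(5, 0.05, 0.5)
  comps$width <- runif(5, 3, 30)
  y0 <- 0.17
  y <- evalCumulative(comps, y0, g)
  idx <- sample(length(g), 20)
  for (i in idx) {
    scalar <- y0
    for (k in 1:5)
      scalar <- scalar + comps$amplitude[k] *
        exp(-0.5 * ((g[i] - comps$center[k]) / comps$width[k])^2)
    expect_lt(abs(y[i] - scalar), 1e-12)
  }

  expect_error(evalCumulative(comps[1:4, ], 0, g), "five")
  bad <- comps; bad$center[1] <- 460
  expect_error(evalCumulative(bad, 0, g), "canonical")
})

test_that("cumulative model is linear in the amplitude vector", {
  g <- fixtureGrid()
  set.seed(8)
  for (rep in 1:5) {
    w <- runif(5, 3, 30)
    a1 <- runif(5); a2 <- runif(5); lam <- runif(1, -2, 2)
    c1 <- data.frame(center = sort(unname(peakCenters)),
                     amplitude = a1, width = w)
    c2 <- transform(c1, amplitude = a2)
    mix <- transform(c1, amplitude = a1 + lam * a2)
    lhs <- evalCumulative(mix, 0, g)
    rhs <- evalCumulative(c1, 0, g) + lam * (evalCumulative(c2, 0, g) -
                                             rep(0, length(g)))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("residual fraction matches a counting loop, inclusive at equality", {
  expect_equal(residualFraction(rep(0, 10)), 1)
  r <- c(rep(0, 97), rep(0.05, 3))
  expect_equal(residualFraction(r, 0.02), 0.97)
  expect_equal(residualFraction(c(0.02, -0.02, 0.0200001), 0.02), 2 / 3)

  set.seed(9)
  x <- rnorm(500, 0, 0.03)
  loop <- 0L
  for (v in x) if (abs(v) <= 0.02) loop <- loop + 1L
  expect_identical(residualFraction(x, 0.02), loop / 500)

  expect_error(residualFraction(numeric(0)), "non-empty")
  expect_error(residualFraction(c(0, 1), tolerance = 0), "positive")
})

test_that("acceptance rule: 97% case splits the 0.95 and 0.98 partitions", {
  g <- fixtureGrid()
  comps <- fixtureComponents()
  y <- evalCumulative(comps, 0.35, g)
  # corrupt exactly 3% of points far outside the band, leaving 97% at zero
  n <- length(g)
  n_bad <- round(0.03 * n)
  resid <- rep(0, n)
  resid[seq_len(n_bad)] <- 0.05
  frac <- (n - n_bad) / n
  expect_equal(residualFraction(resid, 0.02), frac)

  # threshold behaviour on a result carrying exactly that fraction
  res97 <- new("DeconvolutionResult", wavelength = g, observed = y,
               components = transform(comps,
                                      fwhm = 2 * sqrt(2 * log(2)) * width,
                                      at_bound = FALSE),
               offset = 0.35, fitted = y, residuals = resid,
               mse = mean(resid^2), tolerance = 0.02,
               residualFraction = frac, partition = 0.98,
               accepted = frac >= 0.98, convergence = list())
  expect_false(isAccepted(res97))
  expect_true(isAccepted(acceptFit(res97, 0.95)))
  expect_true(isAccepted(acceptFit(res97, 0.90)))
  expect_false(isAccepted(acceptFit(res97, 0.98)))
  expect_error(acceptFit(res97, 0), "partition")
  expect_error(acceptFit(res97, 1.2), "partition")
})

test_that("acceptance is monotone in the partition", {
  g <- fixtureGrid()
  set.seed(10)
  y <- evalCumulative(fixtureComponents(), 0.35, g) +
    rnorm(length(g), 0, 0.01)
  fit <- fitFiveGaussians(AbsorbanceSpectrum(g, y))
  partitions <- sort(runif(10, 0.5, 1))
  acc <- vapply(partitions, function(p) isAccepted(acceptFit(fit, p)), TRUE)
  expect_true(all(diff(as.integer(acc)) <= 0))  # TRUEs before FALSEs
})

test_that("component AUC agrees with the closed-form Gaussian integral", {
  g <- fixtureGrid()
  expect_equal(componentAUC(539.34, 0, 5, g), 0)
  area <- componentAUC(539.34, 1, 5, g)
  expect_lt(abs(area - sqrt(2 * pi) * 5) / (sqrt(2 * pi) * 5), 1e-4)

  # halving the grid spacing barely moves the trapezoidal area
  g2 <- seq(450, 650, by = 0.235)
  area2 <- componentAUC(539.34, 1, 5, g2)
  expect_lt(abs(area2 - area) / area, 1e-6)

  expect_error(componentAUC(539.34, 1, 0, g), "width")
  expect_error(componentAUC(539.34, -1, 5, g), "amplitude")
})

test_that("noiseless five-Gaussian spectra are recovered to 1e-6 relative", {
  g <- fixtureGrid()
  comps <- fixtureComponents()
  y0 <- 0.35
  spec <- AbsorbanceSpectrum(g, evalCumulative(comps, y0, g))
  fit <- fitFiveGaussians(spec)
  est <- components(fit)
  expect_lt(max(abs(est$amplitude - comps$amplitude) / comps$amplitude),
            1e-6)
  expect_lt(max(abs(est$width - comps$width) / comps$width), 1e-6)
  expect_lt(abs(fitOffset(fit) - y0) / y0, 1e-6)
  expect_equal(residualFraction(fit), 1.0)
  expect_true(isAccepted(fit))
  expect_equal(est$fwhm, 2 * sqrt(2 * log(2)) * est$width)
  # optimizer monotonicity: final mse never exceeds the initial-guess mse
  init <- transform(comps, width = 10,
                    amplitude = pmax(0, approx(g, absorbance(spec),
                                               xout = comps$center)$y -
                                        min(absorbance(spec))))
  mse0 <- mean((absorbance(spec) -
                  evalCumulative(init, min(absorbance(spec)), g))^2)
  expect_lte(mse(fit), mse0)
})

test_that("a single active component leaves the others near zero", {
  g <- fixtureGrid()
  comps <- fixtureComponents(amplitude = c(0.4, 0, 0, 0, 0),
                             width = c(15, 7, 6, 5, 25))
  spec <- AbsorbanceSpectrum(g, evalCumulative(comps, 0.1, g))
  # widths of absent components are unconstrained and may drift to a bound
  fit <- suppressWarnings(fitFiveGaussians(spec))
  others <- components(fit)$amplitude[-1]
  expect_true(all(others < 1e-3))
  expect_lt(abs(components(fit)$amplitude[1] - 0.4), 1e-4)
})

test_that("amplitude recovery under seeded noise is unbiased to within 2%", {
  g <- fixtureGrid()
  comps <- fixtureComponents()
  y <- evalCumulative(comps, 0.35, g)
  n_seeds <- 200
  amp_hat <- matrix(NA_real_, n_seeds, 5)
  for (s in seq_len(n_seeds)) {
    set.seed(5000 + s)
    fit <- fitFiveGaussians(AbsorbanceSpectrum(g, y + rnorm(length(g), 0,
                                                            0.005)))
    amp_hat[s, ] <- components(fit)$amplitude
  }
  rel_bias <- abs(colMeans(amp_hat) - comps$amplitude) / comps$amplitude
  expect_true(all(rel_bias < 0.02))
})

test_that("deconvolution results serialize to JSON", {
  g <- fixtureGrid()
  spec <- AbsorbanceSpectrum(g, evalCumulative(fixtureComponents(), 0.35, g))
  fit <- fitFiveGaussians(spec)
  parsed <- jsonlite::fromJSON(deconvolutionToJSON(fit))
  expect_equal(parsed$residual_fraction, 1.0)
  expect_true(parsed$accepted)
  expect_equal(nrow(parsed$components), 5L)
})
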