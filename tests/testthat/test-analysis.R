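test_that("FWHM is exact on closed-form profiles", {
  x <- seq(-6, 6, by = 0.001)
  # semicircle radius r: width at half max is r sqrt(3)
  semi <- data.frame(x = x, height = sqrt(pmax(25 - x^2, 0)))
  expect_equal(fwhm(semi), 5 * sqrt(3), tolerance = 1e-4)
  # triangle of base b: b / 2
  tri <- data.frame(x = x, height = pmax(1 - abs(x) / 3, 0))
  expect_equal(fwhm(tri), 3, tolerance = 1e-4)
  expect_error(fwhm(data.frame(x = x, height = rep(0, length(x)))), "baseline")
})

test_that("FWHM of the dilated hemisphere matches the oracle profile", {
  r <- 5
  tip <- tip20(1)
  hemi <- makeHemisphere(r, spacing = 0.05)
  xs <- seq(-8, 8, by = 0.05)
  img <- zeroForceTopography(tip, hemi, scanX = xs, scanY = 0)
  measured <- fwhm(data.frame(x = xs, height = imageHeights(img)[, 1]))
  # oracle: brute-force dilation on a fine 1-D grid, then half-max crossing
  prof <- vapply(xs, function(x0) bruteDilation(tip, hemi, c(x0, 0)), numeric(1))
  expect_equal(measured, fwhm(data.frame(x = xs, height = prof)),
               tolerance = 1e-9)
  # convolution widens the feature
  expect_gt(measured, fwhm(data.frame(x = xs,
                                      height = sqrt(pmax(r^2 - xs^2, 0)))))
})

test_that("apparent volume integrates exact and dilated hemispheres correctly", {
  r <- 5
  hemi <- makeHemisphere(r, spacing = 0.1)
  Vtrue <- (2 / 3) * pi * r^3
  expect_equal(apparentVolume(hemi), Vtrue, tolerance = 0.01)
  # grid refinement converges at second order: quarter the error at half step
  e1 <- abs(apparentVolume(makeHemisphere(r, spacing = 0.4)) - Vtrue)
  e2 <- abs(apparentVolume(makeHemisphere(r, spacing = 0.2)) - Vtrue)
  expect_lt(e2, e1)
  # half-max footprint restricts the integral
  expect_lt(apparentVolume(hemi, footprint = "halfmax"), apparentVolume(hemi))
})

test_that("cosine projection recovers classical series", {
  lambda <- 10
  x <- seq(0, lambda - lambda / 256, by = lambda / 256)
  # pure cosine
  fs <- fourierCoefficients(data.frame(x = x, height = 3 * cos(2 * pi * x / lambda)),
                            N = 20)
  A <- amplitudes(fs)
  expect_equal(unname(A[2]), 3, tolerance = 1e-10)
  expect_lt(max(abs(A[c(1, 3:21)])), 1e-10)
  # constant profile
  fs0 <- fourierCoefficients(data.frame(x = x, height = rep(2.5, length(x))), N = 10)
  A0 <- amplitudes(fs0)
  expect_equal(unname(A0[1]), 2.5, tolerance = 1e-12)
  expect_lt(max(abs(A0[-1])), 1e-12)
  # symmetric square wave: A_n = (4A/pi)(-1)^((n-1)/2)/n for odd n, 0 for even
  sq <- squareWave(x, lambda)
  fsq <- fourierCoefficients(data.frame(x = x, height = sq), N = 9)
  Asq <- amplitudes(fsq)
  nOdd <- c(1, 3, 5, 7, 9)
  ref <- (4 / pi) * (-1)^((nOdd - 1) / 2) / nOdd
  expect_equal(unname(Asq[nOdd + 1]), ref, tolerance = 0.01)
  expect_lt(max(abs(Asq[c(2, 4, 6, 8) + 1])), 1e-10)
  expect_error(fourierCoefficients(data.frame(x = x^1.1, height = sq)),
               "uniform")
})

test_that("Fourier round trip and Parseval consistency hold", {
  lambda <- 7
  x <- seq(0, lambda - lambda / 128, by = lambda / 128)
  h <- 1 + 2 * cos(2 * pi * x / lambda) + 0.5 * cos(3 * 2 * pi * x / lambda)
  fs <- fourierCoefficients(data.frame(x = x, height = h), N = 30)
  # reconstruct-then-project is the identity on coefficients
  h2 <- reconstructProfile(fs, x)
  fs2 <- fourierCoefficients(data.frame(x = x, height = h2), N = 30)
  expect_equal(amplitudes(fs2), amplitudes(fs), tolerance = 1e-10)
  expect_equal(h2, h, tolerance = 1e-10)
  # Parseval: mean power = A0^2 + sum A_n^2 / 2
  A <- unname(amplitudes(fs))
  expect_equal(mean(h^2), A[1]^2 + sum(A[-1]^2) / 2, tolerance = 1e-10)
})

test_that("higher-order content isolates harmonics beyond the fundamental", {
  lambda <- 10
  x <- seq(0, lambda - lambda / 256, by = lambda / 256)
  pure <- fourierCoefficients(data.frame(x = x, height = cos(2 * pi * x / lambda)),
                              N = 50)
  expect_lt(higherOrderContent(pure), 1e-10)
  sq <- fourierCoefficients(
    data.frame(x = x, height = squareWave(x, lambda)), N = 50)
  expect_gt(higherOrderContent(sq), 0.01)
  # dominated by A_3
  A <- unname(amplitudes(sq))
  expect_equal(max(abs(A[3:51])), abs(A[4]), tolerance = 1e-9)
  expect_gt(higherOrderContent(sq, method = "rss"), higherOrderContent(sq))
})

test_that("modulus fits are self-consistent across the model family", {
  mTrue <- Material(100, 0.3)
  d <- seq(0.01, 0.3, length.out = 25)
  cases <- list(
    list(model = "hertz", F = hertzForce(mTrue, 2, d, r = 6), r = 6, R = 2),
    list(model = "sneddon", F = sneddonForce(mTrue, tip20(2), d), r = Inf, R = 2),
    list(model = "double_contact", F = doubleContactForce(mTrue, 2, 6, d),
         r = 6, R = 2))
  for (cs in cases) {
    fit <- fitModulus(ForceCurve(d, cs$F), cs$model, R = cs$R,
                      theta = pi / 9, r = cs$r)
    expect_lt(abs(fit$E / 100 - 1), 1e-3)
  }
})

test_that("ignoring base compression underestimates the modulus", {
  mTrue <- Material(100, 0.3)
  d <- seq(0.01, 0.3, length.out = 25)
  F <- doubleContactForce(mTrue, 1, 3, d)
  # plain Hertz fit with R in place of R* (the common AFM convention)
  fitH <- fitModulus(ForceCurve(d, F), "hertz", R = 1)
  expect_lt(fitH$E / 100, 1)
  # double-contact fit recovers the generating modulus
  fitD <- fitModulus(ForceCurve(d, F), "double_contact", R = 1, r = 3)
  expect_lt(abs(fitD$E / 100 - 1), 1e-3)
})

test_that("force ceiling clips fits and data requirements are enforced", {
  m <- Material(100, 0.3)
  d <- seq(0.01, 0.6, length.out = 30)
  F <- hertzForce(m, 1, d)
  full <- fitModulus(ForceCurve(d, F), "hertz", R = 1)
  clipped <- fitModulus(ForceCurve(d, F), "hertz", R = 1,
                        forceCeilingRel = 0.1, refMaterial = m)
  expect_lt(clipped$n, full$n)
  expect_lt(abs(clipped$E / 100 - 1), 1e-3)
  expect_error(fitModulus(ForceCurve(d[1:3], F[1:3]), "hertz", R = 1),
               "at least 5")
})

test_that("modulus map is flat on a half-space and recovers E", {
  ax <- seq(-3, 3, 0.25)
  flat <- HeightField(ax, ax, matrix(0, length(ax), length(ax)))
  tip <- tip20(1)
  m <- mat100()
  vol <- buildForceVolume(flat, tip, m, scanX = c(-1, 0, 1), scanY = 0,
                          deltaGrid = defaultDeltaGrid(tip, n = 25))
  mp <- modulusMap(vol, "hertz", forceCeilingRel = 0.1)
  expect_equal(mp$E_AFM, rep(100, 3), tolerance = 1e-3)
})
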