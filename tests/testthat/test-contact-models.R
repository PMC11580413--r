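test_that("Hertz force matches its pressure-distribution integral", {
  m <- matUnit()  # E* = 1
  expect_identical(hertzForce(m, 1, 0), 0)
  # independent oracle: integrate the Hertz pressure p(rho) = p0 sqrt(1 -
  # rho^2/a^2), p0 = 2 E* a / (pi R*), over the contact patch
  for (case in list(c(R = 1, d = 1), c(R = 10, d = 0.5))) {
    a <- sqrt(case[["R"]] * case[["d"]])
    p0 <- 2 * a / (pi * case[["R"]])
    Fnum <- integrate(function(rho) p0 * sqrt(1 - (rho / a)^2) * 2 * pi * rho,
                      0, a, rel.tol = 1e-12)$value
    expect_equal(hertzForce(m, case[["R"]], case[["d"]]), Fnum,
                 tolerance = 1e-9)
  }
  expect_equal(hertzForce(m, 1, 1), 4 / 3, tolerance = 1e-12)
  expect_error(hertzForce(m, 1, -0.1), "nonnegative")
})

test_that("Hertz in dimensionless form: F/(E*R^2) at delta/R = 0.1, R* = R/2", {
  m <- Material(100, 0.3)
  R <- 2
  fc <- ForceCurve(0.1 * R, hertzForce(m, R, 0.1 * R, r = R))  # r = R => R* = R/2
  nd <- nondimensionalize(fc, m, R)
  expect_equal(nd$force_rel, (4 / 3) * sqrt(1 / 2) * 0.1^1.5, tolerance = 1e-12)
  expect_equal(nd$force_rel, 0.0298, tolerance = 1e-3)
})

test_that("conical Sneddon force matches its pressure-distribution integral", {
  m <- matUnit()
  tip <- tip20(1)
  expect_identical(sneddonForce(m, tip, 0), 0)
  # oracle: cone pressure p(r) = (E* d / (pi a)) acosh(a/r), a = (2/pi) tan(th) d
  th <- pi / 9
  d <- 1
  a <- (2 / pi) * tan(th) * d
  Fnum <- integrate(function(r) (d / (pi * a)) * acosh(a / r) * 2 * pi * r,
                    0, a, rel.tol = 1e-10)$value
  expect_equal(sneddonForce(m, tip, d), Fnum, tolerance = 1e-6)
  expect_equal(sneddonForce(m, tip, 1), 0.2317, tolerance = 1e-4)
  # monotone in cone angle
  f <- vapply(c(10, 20, 40, 60), function(th)
    sneddonForce(m, TipGeometry(1, th, degrees = TRUE), 1), numeric(1))
  expect_true(all(diff(f) > 0))
  # the correction function multiplies the pure-cone law
  expect_equal(sneddonForce(m, tip, 2, r = 5, f = function(delta, R, r) 0.5),
               0.5 * sneddonForce(m, tip, 2), tolerance = 1e-12)
})

test_that("force laws scale linearly in E* with the stated log-log exponents", {
  tip <- tip20(1)
  for (Es in c(0.5, 3)) {
    m <- Material(Es, 0)
    expect_equal(hertzForce(m, 1, 0.3) / hertzForce(matUnit(), 1, 0.3), Es,
                 tolerance = 1e-12)
    expect_equal(sneddonForce(m, tip, 0.3) / sneddonForce(matUnit(), tip, 0.3),
                 Es, tolerance = 1e-12)
  }
  m <- mat100()
  sH <- loglogSlope(function(d) hertzForce(m, 1, d), 0.01, 0.1)
  expect_equal(sH, 1.5, tolerance = 1e-9)
  sS <- loglogSlope(function(d) sneddonForce(m, tip, d), 0.01, 0.1)
  expect_equal(sS, 2.0, tolerance = 1e-9)
})

test_that("double-contact inverse round-trips the series-compliance forward map", {
  m <- mat100()
  expect_identical(doubleContactForce(m, 1, 3, 0), 0)
  delta <- c(0.02, 0.1, 0.25)
  F <- doubleContactForce(m, 1, 3, delta)
  fwd <- doubleContactDelta(m, F, effectiveRadius(1, 3), 3)
  expect_equal(fwd$delta, delta, tolerance = 1e-10)
  expect_equal(fwd$deltaI + fwd$deltaC, fwd$delta, tolerance = 1e-12)
  # extra base compliance can only soften the measured response
  expect_true(all(F < hertzForce(m, 1, delta, r = 3)))
})

test_that("double contact reduces to Hertz for r -> Inf and obeys series-spring symmetry", {
  m <- mat100()
  d <- 0.2
  expect_equal(doubleContactForce(m, 1, Inf, d), hertzForce(m, 1, d),
               tolerance = 1e-12)
  # approach to the limit is monotone from below (base compression ~ r^(-1/3))
  Fs <- vapply(c(10, 1000, 1e9), function(r) doubleContactForce(m, 1, r, d),
               numeric(1))
  FH <- hertzForce(m, 1, d)
  expect_true(all(diff(Fs) > 0) && all(Fs < FH))
  expect_lt(abs(Fs[3] / FH - 1), 0.01)
  # equal compliances: delta(F) = 2 delta_Hertz(F) => F(delta) = F_Hertz(delta/2)
  R0 <- 2
  g <- function(F) doubleContactDelta(m, F, R0, R0)$delta - d
  Fsym <- uniroot(g, c(0, hertzForce(Material(100, 0.3), R0, d)), tol = 1e-14)$root
  expect_equal(Fsym, (4 / 3) * reducedModulus(m) * sqrt(R0) * (d / 2)^1.5,
               tolerance = 1e-9)
})

test_that("nondimensionalization is an exact round trip and collapses Hertz curves", {
  m <- Material(37, 0.21)
  R <- 3.1
  fc <- ForceCurve(c(0.1, 0.4, 0.9), c(2, 11, 40))
  nd <- nondimensionalize(fc, m, R)
  back <- dimensionalize(nd, m, R)
  expect_equal(indentation(back), indentation(fc), tolerance = 1e-14)
  expect_equal(forces(back), forces(fc), tolerance = 1e-14)
  # unit identity: 1 pN / (1 MPa x 1 nm^2) = 1
  nd1 <- nondimensionalize(ForceCurve(1, 1), matUnit(), 1)
  expect_equal(nd1$force_rel, 1, tolerance = 1e-15)
  # Hertz curves collapse as r/R grows: F_rel at fixed delta/R approaches the
  # flat-sample value with gap shrinking like R*/R = r/(r + R)
  dRel <- 0.2
  flat <- (4 / 3) * dRel^1.5
  gaps <- vapply(c(2, 4, 8), function(ratio) {
    Fr <- hertzForce(matUnit(), 1, dRel, r = ratio) / 1
    abs(Fr - flat) / flat
  }, numeric(1))
  expect_true(all(gaps < 0.2))
  expect_true(all(diff(gaps) < 0))
})

test_that("force curves round-trip through CSV including the displacement split", {
  m <- mat100()
  d <- seq(0.01, 0.3, length.out = 8)
  F <- doubleContactForce(m, 1, 3, d)
  split <- doubleContactDelta(m, F, effectiveRadius(1, 3), 3)
  fc <- ForceCurve(split$delta, F, deltaI = split$deltaI, deltaC = split$deltaC)
  path <- tempfile(fileext = ".csv")
  writeForceCurve(fc, path)
  back <- readForceCurve(path)
  expect_equal(indentation(back), indentation(fc), tolerance = 1e-6)
  expect_equal(forces(back), forces(fc), tolerance = 1e-6)
  expect_equal(back@deltaI, fc@deltaI, tolerance = 1e-6)
})
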