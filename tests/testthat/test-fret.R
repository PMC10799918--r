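test_that("molarExtinction inverts Beer-Lambert", {
  grid <- 260:300
  a <- Spectrum(grid, rep(0.0876, length(grid)), kind = "absorbance")
  eps <- molarExtinction(a, concM = 2e-6)
  # recovers the canonical BSA coefficient (~43,824 M^-1 cm^-1) at 280 nm
  expect_equal(intensityAt(eps, 280), 43800, tolerance = 1e-9)
  zero <- Spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  expect_equal(intensities(molarExtinction(zero, 2e-6)),
               rep(0, length(grid)))
  # doubling the path length halves epsilon
  expect_equal(intensities(molarExtinction(a, 2e-6, pathlengthCm = 2)),
               intensities(eps) / 2, tolerance = 1e-12)
  expect_error(molarExtinction(a, 0), "positive")
  expect_error(molarExtinction(a, 2e-6, 0), "positive")
})

test_that("overlapIntegral reproduces the constant-spectra closed form", {
  grid <- seq(285, 450, by = 1)
  Fv <- Spectrum(grid, rep(7, length(grid)))   # any constant: J-normalized
  ev <- Spectrum(grid, rep(1, length(grid)), kind = "absorbance")
  J <- overlapIntegral(Fv, ev)
  closed <- (450^5 - 285^5) / (5 * 165)        # integral(l^4)/integral(1)
  expect_equal(J, closed, tolerance = 1e-4)
  # zero extinction: J = 0
  zero <- Spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  expect_equal(overlapIntegral(Fv, zero), 0)
})

test_that("overlapIntegral agrees with a 100x-finer quadrature oracle", {
  grid <- seq(285, 450, by = 1)
  donor <- function(x) gaussianBand(x, 340, 15, 1000)
  eps <- function(x) gaussianBand(x, 300, 20, 1e4)
  J <- overlapIntegral(Spectrum(grid, donor(grid)),
                       Spectrum(grid, eps(grid), kind = "absorbance"))
  fine <- seq(285, 450, by = 0.01)
  Jfine <- pracma::trapz(fine, donor(fine) * eps(fine) * fine^4) /
    pracma::trapz(fine, donor(fine))
  expect_equal(J, Jfine, tolerance = 1e-3)
})

test_that("overlapIntegral is invariant under donor scaling and validates windows", {
  grid <- seq(285, 450, by = 1)
  d1 <- Spectrum(grid, gaussianBand(grid, 340, 15, 1000))
  d2 <- Spectrum(grid, gaussianBand(grid, 340, 15, 52000))
  eps <- Spectrum(grid, gaussianBand(grid, 300, 20, 1e4),
                  kind = "absorbance")
  expect_equal(overlapIntegral(d1, eps), overlapIntegral(d2, eps),
               tolerance = 1e-12)
  expect_error(overlapIntegral(Spectrum(300:450, rep(1, 151)), eps),
               "donor.*window")
  expect_error(overlapIntegral(d1, Spectrum(300:450, rep(1, 151),
                                            kind = "absorbance")),
               "acceptor.*window")
  flat0 <- Spectrum(grid, rep(0, length(grid)))
  expect_error(overlapIntegral(flat0, eps), "zero")
})

test_that("forsterRadius reproduces the published radii", {
  # kappa^2 = 0.476, phiD = 0.15, eta^-4 = 0.3139
  expect_equal(forsterRadius(1.33e14), 2.53, tolerance = 2e-3)
  expect_equal(forsterRadius(5.35e12), 1.48, tolerance = 2e-3)
  # sixth-root power law: 64x J doubles R0
  expect_equal(forsterRadius(64 * 5.35e12), 2 * forsterRadius(5.35e12),
               tolerance = 1e-12)
  # monotone in every factor
  base <- forsterRadius(1e13)
  expect_gt(forsterRadius(2e13), base)
  expect_gt(forsterRadius(1e13, kappa2 = 2 / 3), base)
  expect_gt(forsterRadius(1e13, phiD = 0.2), base)
  expect_gt(forsterRadius(1e13, etaInv4 = 0.4), base)
  expect_error(forsterRadius(-1), "positive")
  expect_error(forsterRadius(1e13, phiD = 0), "positive")
})

test_that("efficiency and distance invert each other", {
  expect_identical(fretEfficiency(100, 100), 0)
  expect_identical(fretEfficiency(0, 100), 1)
  expect_equal(fretEfficiency(92.3, 100), 0.077, tolerance = 1e-12)
  expect_error(fretEfficiency(101, 100), "exceeds")
  expect_error(fretEfficiency(1, 0), "positive")
  expect_equal(donorAcceptorDistance(0.077, 2.53), 3.83, tolerance = 1e-3)
  expect_equal(donorAcceptorDistance(0.076, 1.48), 2.244, tolerance = 1e-3)
  expect_equal(donorAcceptorDistance(0.5, 1.9), 1.9, tolerance = 1e-12)
  expect_error(donorAcceptorDistance(0, 2), "inside")
  expect_error(donorAcceptorDistance(1, 2), "inside")
  # roundtrip E -> r -> E to 1e-12
  for (E in c(0.05, 0.077, 0.3, 0.9)) {
    r <- donorAcceptorDistance(E, 2.53)
    expect_equal(2.53^6 / (2.53^6 + r^6), E, tolerance = 1e-12)
  }
})

test_that("fretValidity applies the distance windows", {
  expect_true(fretValidity(2.0, 1.9)$validRange)
  expect_false(fretValidity(2 * 1.9, 1.9)$validRange)
  expect_true(fretValidity(3.83, 2.53)$within10nm)
  expect_false(fretValidity(12, 2.53)$within10nm)
  expect_error(fretValidity(-1, 2), "positive")
})

test_that("fretAnalysis chains the computations self-consistently", {
  grid <- seq(285, 450, by = 1)
  donor <- Spectrum(grid, gaussianBand(grid, 340, 15, 1000))
  absb <- Spectrum(grid, gaussianBand(grid, 300, 20, 0.05),
                   kind = "absorbance")
  res <- fretAnalysis(donor, absb, acceptorConcM = 5e-6, F = 92.3, F0 = 100)
  expect_s4_class(res, "FretResult")
  expect_equal(res@efficiencyE, 0.077, tolerance = 1e-12)
  # slots satisfy the transfer law and the component functions
  eps <- molarExtinction(absb, 5e-6)
  expect_equal(res@JMcmNm4, overlapIntegral(donor, eps))
  expect_equal(res@R0Nm, forsterRadius(res@JMcmNm4))
  expect_equal(res@R0Nm^6 / (res@R0Nm^6 + res@rNm^6), res@efficiencyE,
               tolerance = 1e-12)
  expect_true(res@within10nm)
  expect_error(fretAnalysis(donor, absb, 5e-6), "supply either")
})
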