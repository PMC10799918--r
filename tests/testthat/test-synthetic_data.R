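test_that("equal seeds give bit-identical series; seeds matter", {
  cfg <- simulationConfig("hill_binding", KaM = 3897, nSites = 0.89,
                          noiseRel = 0.02, seed = 99)
  a <- simulateTitration(cfg)
  b <- simulateTitration(cfg)
  expect_identical(assay(a, "signal"), assay(b, "signal"))
  cfg2 <- simulationConfig("hill_binding", KaM = 3897, nSites = 0.89,
                           noiseRel = 0.02, seed = 100)
  expect_false(identical(assay(a, "signal"),
                         assay(simulateTitration(cfg2), "signal")))
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(simulateTitration(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless linear model follows the Stern-Volmer closed form", {
  cfg <- simulationConfig("stern_volmer_linear", KsvM = 1.92e4, seed = 1)
  ts <- simulateTitration(cfg)
  f <- intensityAt(ts, 340)
  # F0/F at 80 uM = 1 + 1.92e4 * 8e-5 = 2.536
  expect_equal(unname(f[1] / f[10]), 2.536, tolerance = 1e-12)
  # zero-quencher trace equals the unquenched band exactly
  expect_equal(assay(ts, "signal")[, 1],
               gaussianBand(285:450, 340, 15, 1000))
})

test_that("hill model with n = 1 coincides with the linear model", {
  K <- 7.3e3
  lin <- simulateTitration(simulationConfig("stern_volmer_linear",
                                            KsvM = K, seed = 2))
  hill <- simulateTitration(simulationConfig("hill_binding", KaM = K,
                                             nSites = 1, seed = 2))
  expect_equal(assay(lin, "signal"), assay(hill, "signal"),
               tolerance = 1e-12)
})

test_that("noiseless fits recover the generative constants", {
  svf <- sternVolmerFit(simulateTitration(
    simulationConfig("stern_volmer_linear", KsvM = 1.92e4, seed = 4)))
  expect_equal(ksv(svf), 1.92e4, tolerance = 1e-9)
  expect_equal(rSquared(svf), 1, tolerance = 1e-12)
  blf <- doubleLogFit(simulateTitration(
    simulationConfig("hill_binding", KaM = 3897, nSites = 0.89, seed = 4)))
  expect_equal(ka(blf), 3897, tolerance = 1e-6)
  expect_equal(nSites(blf), 0.89, tolerance = 1e-6)
  # the spec's second reference system
  blf2 <- doubleLogFit(simulateTitration(
    simulationConfig("hill_binding", KaM = 14581, nSites = 0.98, seed = 4)))
  expect_equal(ka(blf2), 14581, tolerance = 1e-6)
  expect_equal(nSites(blf2), 0.98, tolerance = 1e-6)
})

test_that("temperature sets encode an exact van't Hoff law", {
  # closed form: dH = 18930 J/mol, dS = 130.14 J/mol/K at 310 K
  expect_equal(kaFromThermo(18930, 130.14, 310), 4057.545,
               tolerance = 1e-6)
  # dH = 0: Ka identical at all temperatures
  expect_equal(kaFromThermo(0, 50, c(290, 300, 310)),
               rep(exp(50 / 8.314), 3))
  # dS = 0: Ka -> 1 as T -> infinity
  expect_equal(kaFromThermo(18930, 0, 1e9), 1, tolerance = 1e-5)
  expect_error(kaFromThermo(100, 10, -5), "positive")
  cfg <- simulationConfig("hill_binding", nSites = 0.89,
                          thermo = list(dH_J_mol = 18930,
                                        dS_J_mol_K = 130.14),
                          seed = 6)
  expect_error(simulateTemperatureSet(cfg, temperaturesK = c(0, 300)),
               "positive")
  series <- simulateTemperatureSet(cfg)
  expect_named(series, c("290", "300", "310"))
  # full chain at noise 0 recovers (dH, dS) essentially exactly
  th <- vantHoff(lapply(series, doubleLogFit))
  expect_equal(deltaH(th), 18.930, tolerance = 1e-6)
  expect_equal(deltaS(th), 130.14, tolerance = 1e-6)
})

test_that("simulateTemperatureSet requires the thermo block", {
  cfg <- simulationConfig("hill_binding", KaM = 3897, nSites = 0.89,
                          seed = 1)
  expect_error(simulateTemperatureSet(cfg), "thermo")
})

test_that("simulated absorbance obeys Beer-Lambert linearity", {
  cfg <- simulationConfig("stern_volmer_linear", KsvM = 1e4, seed = 1,
                          acceptorBand = list(centerNm = 300, widthNm = 20,
                                              epsMax = 1e4))
  sp <- simulateAbsorbance(cfg, concsM = c(0, 2e-6, 4e-6))
  expect_equal(intensities(sp[[1]]), rep(0, 166))       # zero conc
  expect_equal(intensities(sp[[3]]), 2 * intensities(sp[[2]]),
               tolerance = 1e-12)                        # doubling conc
  # band integral scales linearly with the amplitude parameter
  cfg2 <- simulationConfig("stern_volmer_linear", KsvM = 1e4, seed = 1,
                           acceptorBand = list(centerNm = 300, widthNm = 20,
                                               epsMax = 3.5e4))
  sp2 <- simulateAbsorbance(cfg2, concsM = 2e-6)
  int1 <- pracma::trapz(285:450, intensities(sp[[2]]))
  int2 <- pracma::trapz(285:450, intensities(sp2[[1]]))
  expect_equal(int2 / int1, 3.5, tolerance = 1e-9)
  expect_error(simulateAbsorbance(cfg, concsM = -1e-6), "negative")
  expect_error(simulateAbsorbance(
    simulationConfig("stern_volmer_linear", KsvM = 1e4, seed = 1)),
    "acceptorBand")
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig("sphere_of_action", KsvM = 1), "arg")
  expect_error(simulationConfig("stern_volmer_linear", KsvM = -2),
               "positive")
  expect_error(simulationConfig("hill_binding", KaM = 100, nSites = 0.9,
                                noiseRel = -0.1), "noiseRel")
  expect_error(simulationConfig("stern_volmer_linear", KsvM = 1e4,
                                concsM = c(2e-6, 1e-6)), "increasing")
})

test_that("noisy recovery: median Ksv within 2%, median n within 0.05", {
  ksvs <- vapply(1:200, function(s)
    ksv(sternVolmerFit(simulateTitration(
      simulationConfig("stern_volmer_linear", KsvM = 1.92e4,
                       noiseRel = 0.01, seed = s)))), numeric(1))
  expect_lt(abs(median(ksvs) - 1.92e4) / 1.92e4, 0.02)
  ns <- vapply(1:200, function(s)
    nSites(suppressWarnings(doubleLogFit(simulateTitration(
      simulationConfig("hill_binding", KaM = 3897, nSites = 0.89,
                       noiseRel = 0.01, seed = s))))), numeric(1))
  expect_lt(abs(median(ns) - 0.89), 0.05)
})

test_that("Ka recovery is unbiased once the noise-dominated lowest point is dropped", {
  # At 1 uM the quench fraction (~1.8%) is comparable to the 1% noise;
  # log-transform skew there biases the intercept. Subsetting the series
  # to concentrations where signal exceeds noise restores the estimate.
  kas <- vapply(1:200, function(s) {
    ts <- simulateTitration(simulationConfig("hill_binding", KaM = 3897,
                                             nSites = 0.89,
                                             noiseRel = 0.01, seed = s))
    ka(suppressWarnings(doubleLogFit(ts[, -2])))
  }, numeric(1))
  expect_lt(abs(median(kas) - 3897) / 3897, 0.05)
})
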