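test_that("Spectrum construction enforces its invariants", {
  expect_error(Spectrum(c(300, 300, 301), c(1, 2, 3)), "increasing")
  expect_error(Spectrum(c(300), c(1)), "2 points")
  expect_error(Spectrum(300:302, c(1, NA, 3)), "finite")
  expect_error(Spectrum(300:302, c(1, 2)), "equal length")
  # negative absorbance is clipped with a warning, not kept
  expect_warning(s <- Spectrum(300:302, c(-0.1, 0.2, 0.3),
                               kind = "absorbance"), "clipped")
  expect_equal(intensities(s), c(0, 0.2, 0.3))
})

test_that("intensityAt interpolates linearly and is exact at grid points", {
  s <- Spectrum(c(339, 341, 345), c(1, 3, 3))
  expect_identical(intensityAt(s, 341), 3)
  expect_equal(intensityAt(s, 340), 2)  # midpoint of a linear segment
  expect_error(intensityAt(s, 338), "outside grid range")
  expect_error(intensityAt(s, 346), "outside grid range")
  # Gaussian band queried at its center recovers the amplitude
  grid <- seq(285, 450, by = 0.5)
  g <- Spectrum(grid, gaussianBand(grid, 340, 15, 1234.5))
  expect_equal(intensityAt(g, 340), 1234.5, tolerance = 1e-6)
})

test_that("peakPosition finds band maxima with the short-wavelength tie rule", {
  grid <- 285:450
  expect_equal(peakPosition(Spectrum(grid, gaussianBand(grid, 340, 15))), 340)
  # flat trace: tie broken toward the shorter wavelength
  flat <- Spectrum(grid, rep(1, length(grid)))
  expect_equal(peakPosition(flat), 285)
  expect_equal(peakPosition(flat, windowNm = c(300, 320)), 300)
  # two bands, taller one at 301: window restricted search
  two <- Spectrum(grid, gaussianBand(grid, 301, 8, 500) +
                        gaussianBand(grid, 342, 15, 400))
  expect_equal(peakPosition(two, windowNm = c(285, 320)), 301)
  expect_error(peakPosition(two, windowNm = c(500, 510)), "overlap")
})

test_that("peakPosition is invariant under uniform positive scaling", {
  grid <- 285:450
  set.seed(11)
  for (center in c(301, 320, 342)) {
    v <- gaussianBand(grid, center, 10, 100) + runif(length(grid), 0, 1)
    p1 <- peakPosition(Spectrum(grid, v))
    p2 <- peakPosition(Spectrum(grid, 3.7 * v))
    expect_identical(p1, p2)
  }
})

test_that("subtractBackground removes an added band exactly", {
  grid <- 285:450
  a <- gaussianBand(grid, 340, 15, 800)
  b <- gaussianBand(grid, 300, 10, 200)
  total <- Spectrum(grid, a + b)
  recovered <- subtractBackground(total, Spectrum(grid, b))
  expect_equal(intensities(recovered), a, tolerance = 1e-12)
  # self-subtraction and zero background
  s <- Spectrum(grid, a)
  expect_equal(intensities(subtractBackground(s, s)), rep(0, length(grid)))
  expect_equal(intensities(subtractBackground(s, Spectrum(grid, rep(0, length(grid))))), a)
})

test_that("subtractBackground interpolates mismatched grids, forbids extrapolation", {
  gridS <- 300:400
  gridB <- seq(280, 420, by = 2)   # coarser but covering grid
  lin <- function(x) 0.5 + 0.01 * x  # linear, so interpolation is exact
  s <- Spectrum(gridS, rep(5, length(gridS)))
  out <- subtractBackground(s, Spectrum(gridB, lin(gridB)))
  expect_equal(intensities(out), 5 - lin(gridS), tolerance = 1e-12)
  expect_error(
    subtractBackground(Spectrum(250:420, rep(1, 171)),
                       Spectrum(gridB, lin(gridB))),
    "extrapolation")
})

test_that("inner-filter correction applies exp((Aex + Aem)/2) per wavelength", {
  grid <- 285:450
  cfg <- simulationConfig("stern_volmer_linear", KsvM = 1.92e4, seed = 5)
  ts <- simulateTitration(cfg)
  nconc <- length(paperConcsM)
  # zero absorbance: identity
  zero <- Spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  out0 <- innerFilterCorrect(ts, rep(0, nconc), zero)
  expect_equal(assay(out0, "signal"), assay(ts, "signal"))
  expect_true(isCorrected(out0))
  # Aex + Aem = 2 scales by e; Aex=0.10, Aem=0.05 scales by exp(0.075)
  aem1 <- Spectrum(grid, rep(1, length(grid)), kind = "absorbance")
  out1 <- innerFilterCorrect(ts, rep(1, nconc), aem1)
  expect_equal(assay(out1, "signal"), assay(ts, "signal") * exp(1),
               tolerance = 1e-12)
  aem05 <- Spectrum(grid, rep(0.05, length(grid)), kind = "absorbance")
  out2 <- innerFilterCorrect(ts, rep(0.10, nconc), aem05)
  expect_equal(assay(out2, "signal") / assay(ts, "signal"),
               matrix(1.077884, nrow(ts), ncol(ts)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # wavelength-dependent Aem is evaluated per emission wavelength
  aemRamp <- Spectrum(grid, seq(0, 0.4, length.out = length(grid)),
                      kind = "absorbance")
  out3 <- innerFilterCorrect(ts, rep(0, nconc), aemRamp)
  expect_equal(assay(out3, "signal")[, 1],
               assay(ts, "signal")[, 1] * exp(intensities(aemRamp) / 2),
               tolerance = 1e-12)
  # the correction never decreases any intensity
  expect_true(all(assay(out3, "signal") >= assay(ts, "signal")))
  # contract errors
  expect_error(innerFilterCorrect(out1, rep(0, nconc), zero),
               "already")
  expect_error(innerFilterCorrect(ts, rep(-0.1, nconc), zero), "negative")
  expect_error(innerFilterCorrect(ts, rep(0, 3), zero), "3 entries")
})

test_that("titration CSV/JSON roundtrip is bit-identical", {
  cfg <- simulationConfig("hill_binding", KaM = 3897, nSites = 0.89,
                          noiseRel = 0.01, seed = 17)
  ts <- simulateTitration(cfg, temperatureK = 310)
  ts@competitor <- list(name = "warfarin", concM = 2e-6)
  csv <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".json")
  writeTitration(ts, csv, meta)
  back <- loadTitration(csv, meta)
  expect_identical(wavelengths(back), wavelengths(ts))
  expect_identical(assay(back, "signal"), assay(ts, "signal"))
  expect_identical(quencherConcs(back), quencherConcs(ts))
  expect_identical(temperatureK(back), 310)
  expect_identical(excitationNm(back), 280)
  expect_identical(fluorophoreConc(back), 2e-6)
  expect_identical(competitorInfo(back), list(name = "warfarin", concM = 2e-6))
})

test_that("loadTitration validates files and converts micromolar units", {
  csv <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".json")
  grid <- 300:310
  tab <- data.frame(wavelength_nm = grid, I_1 = grid * 0 + 1,
                    I_2 = grid * 0 + 0.5, I_3 = grid * 0 + 0.25)
  utils::write.csv(tab, csv, row.names = FALSE)
  writeMeta <- function(m) jsonlite::write_json(m, meta, auto_unbox = TRUE)
  base <- list(temperature_K = 310, excitation_nm = 280,
               fluorophore_conc = 2, quencher_concs = c(0, 20, 80),
               units = "uM")
  writeMeta(base)
  ts <- loadTitration(csv, meta)
  expect_equal(quencherConcs(ts), c(0, 2e-5, 8e-5))  # uM -> M
  expect_equal(fluorophoreConc(ts), 2e-6)
  # concentration-count mismatch
  writeMeta(modifyList(base, list(quencher_concs = c(0, 20, 40, 80))))
  expect_error(loadTitration(csv, meta), "3 intensity columns.*4")
  # missing units
  writeMeta(base[setdiff(names(base), "units")])
  expect_error(loadTitration(csv, meta), "'units'")
  # bad units value
  writeMeta(modifyList(base, list(units = "mM")))
  expect_error(loadTitration(csv, meta), "uM")
  # missing wavelength column
  writeMeta(base)
  utils::write.csv(setNames(tab, c("wl", "I_1", "I_2", "I_3")), csv,
                   row.names = FALSE)
  expect_error(loadTitration(csv, meta), "wavelength_nm")
  # non-monotone wavelengths
  tab2 <- tab[c(2, 1, 3:11), ]
  utils::write.csv(tab2, csv, row.names = FALSE)
  expect_error(loadTitration(csv, meta), "increasing")
  # single-spectrum file with conc 0 is a valid F0 reference
  utils::write.csv(tab[c("wavelength_nm", "I_1")], csv, row.names = FALSE)
  writeMeta(modifyList(base, list(quencher_concs = 0)))
  ts0 <- loadTitration(csv, meta)
  expect_equal(ncol(ts0), 1L)
  expect_equal(quencherConcs(ts0), 0)
})

test_that("synchronousShift classifies programmed band drifts", {
  # -2 nm drift at the top concentration (tryptophan blueshift scenario)
  mkSync <- function(driftNm) {
    cfg <- simulationConfig("stern_volmer_linear", KsvM = 1.92e4,
                            bandDriftNmPerM = driftNm / 8e-5,
                            band = list(centerNm = 342, widthNm = 15,
                                        amplitude = 1000),
                            seed = 3, scanKind = "synchronous",
                            scanOffsetNm = 60)
    simulateTitration(cfg)
  }
  blue <- synchronousShift(mkSync(-2), 60)
  expect_equal(blue@shiftNm, -2)
  expect_identical(blue@direction, "blueshift")
  expect_equal(unname(blue@peakNmByConc[c(1, 10)]), c(342, 340))
  red <- synchronousShift(mkSync(3), 60)
  expect_equal(red@shiftNm, 3)
  expect_identical(red@direction, "redshift")
  none <- synchronousShift(mkSync(0), 60)
  expect_equal(none@shiftNm, 0)
  expect_identical(none@direction, "none")
  # sub-resolution drift (< half the 1 nm grid step) is not a shift claim
  tiny <- synchronousShift(mkSync(-0.4), 60)
  expect_identical(tiny@direction, "none")
  # contract errors
  emis <- simulateTitration(simulationConfig("stern_volmer_linear",
                                             KsvM = 1e4, seed = 1))
  expect_error(synchronousShift(emis, 60), "not a synchronous scan")
  one <- mkSync(0)[, 1]
  expect_error(synchronousShift(one, 60), "at least 2")
  expect_error(synchronousShift(mkSync(0), 30), "15 or 60")
})
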