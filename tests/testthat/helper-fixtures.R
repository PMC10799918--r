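# Shared fixtures: everything is generated in code, no files on disk.

# closed-form two-parameter OLS, kept independent of stats::lm
olsOracle <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

paperConcsM <- c(0, 1e-06, 5e-06, 1e-05, 2e-05,
                 3e-05, 4e-05, 5e-05, 6e-05, 8e-05)

makeQuenchFit <- function(KsvM, temperatureK, tau0S = 6.2e-9) {
  new("QuenchFit", KsvM = KsvM, KsvSeM = 0, kqMs = KsvM / tau0S,
      tau0S = tau0S, interceptF0F = 1, rSquared = 1,
      temperatureK = temperatureK, nPoints = 10L,
      conclusive = KsvM > 0)
}

makeBindingFit <- function(KaM, nSites, temperatureK,
                           competitor = "", geom = 1.5) {
  new("BindingFit", KaM = KaM, geomErrorFactor = geom, nSites = nSites,
      nSitesSe = 0.04, rSquared = 0.99, temperatureK = temperatureK,
      competitor = competitor, nPoints = 9L)
}

# flat (unquenched) series: identical spectra at every concentration
makeFlatSeries <- function(concsM = paperConcsM, temperatureK = 310) {
  grid <- 285:450
  band <- gaussianBand(grid, 340, 15, 1000)
  mat <- matrix(rep(band, length(concsM)), ncol = length(concsM))
  TitrationSeries(mat, quencherConcsM = concsM, wavelengthsNm = grid,
                  temperatureK = temperatureK)
}
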