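#' Gas constant, J mol^-1 K^-1
#' @export
GAS_CONSTANT <- 8.314

# Default study design: 2 uM fluorophore titrated with 0-80 uM quencher
# (10 points) at 290/300/310 K, excitation 280 nm, emission 285-450 nm
# on a 1 nm grid.
.DEFAULT_CONCS_M <- c(0, 1e-06, 5e-06, 1e-05, 2e-05,
                      3e-05, 4e-05, 5e-05, 6e-05, 8e-05)
.DEFAULT_TEMPS_K <- c(290, 300, 310)
.DEFAULT_GRID_NM <- seq(285, 450, by = 1)

#' Build a simulation configuration
#'
#' Defines a forward model of a fluorescence quenching titration with
#' known ground truth. Quenching models:
#' \describe{
#'   \item{`stern_volmer_linear`}{`F = F0 / (1 + Ksv * Q)` — the generative
#'     inverse of the Stern-Volmer relation.}
#'   \item{`hill_binding`}{`F = F0 / (1 + Ka * Q^n)` — the generative
#'     inverse of the double-logarithmic binding relation.}
#'   \item{`combined`}{product of both attenuation factors.}
#' }
#' When `thermo` is given, `Ka(T) = exp(-dH/(R*T) + dS/R)` replaces `KaM`,
#' so a temperature set carries an exact van't Hoff line as ground truth.
#' Noise is multiplicative Gaussian (sigma = `noiseRel` x signal),
#' truncated at +/- 5 sigma so intensities stay positive.
#'
#' @param quenchingModel `"stern_volmer_linear"`, `"hill_binding"` or
#'   `"combined"`.
#' @param KsvM,KaM,nSites model parameters (see above).
#' @param thermo `NULL` or `list(dH_J_mol=, dS_J_mol_K=)`.
#' @param band emission band, `list(centerNm=, widthNm=, amplitude=)`.
#' @param bandDriftNmPerM linear drift of the band center with quencher
#'   concentration (nm per M); used to emulate synchronous-scan
#'   blueshifts/redshifts.
#' @param acceptorBand `NULL` or `list(centerNm=, widthNm=, epsMax=)`
#'   describing the acceptor's molar extinction band (epsMax in
#'   M^-1 cm^-1) for absorbance / FRET fixtures.
#' @param noiseRel relative noise sigma (0 = noiseless).
#' @param seed integer RNG seed.
#' @param concsM,temperaturesK,gridNm,excitationNm,fluorophoreConcM study
#'   design; defaults emulate a 2 uM protein titrated with 0-80 uM ligand
#'   at 290/300/310 K, emission 285-450 nm at 1 nm.
#' @param scanKind,scanOffsetNm emit emission or synchronous scans.
#' @return A [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig("stern_volmer_linear", KsvM = 1.92e4, seed = 1)
#' ts <- simulateTitration(cfg)
#' sternVolmerFit(ts)
#' @export
simulationConfig <- function(quenchingModel = c("stern_volmer_linear",
                                                "hill_binding", "combined"),
                             KsvM = NA_real_, KaM = NA_real_,
                             nSites = NA_real_, thermo = NULL,
                             band = list(centerNm = 340, widthNm = 15,
                                         amplitude = 1000),
                             bandDriftNmPerM = 0,
                             acceptorBand = NULL,
                             noiseRel = 0, seed = 1L,
                             concsM = .DEFAULT_CONCS_M,
                             temperaturesK = .DEFAULT_TEMPS_K,
                             gridNm = .DEFAULT_GRID_NM,
                             excitationNm = 280,
                             fluorophoreConcM = 2e-6,
                             scanKind = c("emission", "synchronous"),
                             scanOffsetNm = NA_real_) {
  quenchingModel <- match.arg(quenchingModel)
  scanKind <- match.arg(scanKind)
  new("SimulationConfig",
      quenchingModel = quenchingModel,
      KsvM = as.numeric(KsvM), KaM = as.numeric(KaM),
      nSites = as.numeric(nSites),
      thermo = if (is.null(thermo)) list() else thermo,
      band = band, bandDriftNmPerM = as.numeric(bandDriftNmPerM),
      acceptorBand = if (is.null(acceptorBand)) list() else acceptorBand,
      noiseRel = as.numeric(noiseRel), seed = as.integer(seed),
      concsM = as.numeric(concsM),
      temperaturesK = as.numeric(temperaturesK),
      gridNm = as.numeric(gridNm),
      excitationNm = as.numeric(excitationNm),
      fluorophoreConcM = as.numeric(fluorophoreConcM),
      scanKind = scanKind, scanOffsetNm = as.numeric(scanOffsetNm))
}

#' Binding constant at a temperature from a van't Hoff parameter pair
#'
#' `Ka(T) = exp(-dH/(R*T) + dS/R)` with R = 8.314 J mol^-1 K^-1.
#'
#' @param dHJmol enthalpy, J mol^-1.
#' @param dSJmolK entropy, J mol^-1 K^-1.
#' @param temperatureK temperature, K (> 0).
#' @param R gas constant, J mol^-1 K^-1.
#' @return binding constant, M^-1.
#' @export
kaFromThermo <- function(dHJmol, dSJmolK, temperatureK, R = GAS_CONSTANT) {
  if (any(temperatureK <= 0)) stop("temperature must be positive kelvin")
  exp(-dHJmol / (R * temperatureK) + dSJmolK / R)
}

.effectiveKa <- function(config, temperatureK) {
  if (length(config@thermo))
    kaFromThermo(config@thermo$dH_J_mol, config@thermo$dS_J_mol_K,
                 temperatureK)
  else config@KaM
}

.quenchFactor <- function(config, concsM, temperatureK) {
  f <- rep(1, length(concsM))
  if (config@quenchingModel %in% c("stern_volmer_linear", "combined"))
    f <- f * (1 + config@KsvM * concsM)
  if (config@quenchingModel %in% c("hill_binding", "combined")) {
    ka <- .effectiveKa(config, temperatureK)
    f <- f * (1 + ka * concsM^config@nSites)
  }
  f
}

.truncNorm <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  z <- rnorm(n, sd = sd)
  pmin(pmax(z, -5 * sd), 5 * sd)
}

#' Simulate one fluorescence titration
#'
#' Emits a Gaussian emission band on the configured grid, attenuated per
#' quencher concentration by the configured quenching model, with seeded
#' multiplicative noise. Identical seeds give bit-identical output; each
#' design temperature draws from an independent, reproducible substream.
#'
#' @param config a [SimulationConfig-class].
#' @param temperatureK which design temperature to simulate (default: the
#'   first).
#' @return A [TitrationSeries-class].
#' @export
simulateTitration <- function(config, temperatureK = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(temperatureK)) temperatureK <- config@temperaturesK[1L]
  if (temperatureK <= 0) stop("temperature must be positive kelvin")
  tIdx <- match(temperatureK, config@temperaturesK)
  if (is.na(tIdx)) tIdx <- 1L
  grid <- config@gridNm
  concs <- config@concsM
  factor <- .quenchFactor(config, concs, temperatureK)
  # fixed RNG algorithm so fixtures are portable across R releases
  withr_state <- .Random.seed_exists()
  set.seed(config@seed + 7919L * (tIdx - 1L),
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit(withr_state())
  mat <- matrix(0, nrow = length(grid), ncol = length(concs))
  for (i in seq_along(concs)) {
    center <- config@band$centerNm + config@bandDriftNmPerM * concs[i]
    clean <- gaussianBand(grid, center, config@band$widthNm,
                          config@band$amplitude) / factor[i]
    noise <- .truncNorm(length(grid), config@noiseRel)
    mat[, i] <- clean * (1 + noise)
  }
  TitrationSeries(mat, quencherConcsM = concs, wavelengthsNm = grid,
                  temperatureK = temperatureK,
                  excitationNm = config@excitationNm,
                  fluorophoreConcM = config@fluorophoreConcM,
                  scanKind = config@scanKind,
                  scanOffsetNm = config@scanOffsetNm)
}

# Save/restore the global RNG state so simulation never perturbs a user's
# random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Simulate a full temperature set
#'
#' One titration per design temperature, with `Ka(T)` derived from the
#' configured (dH, dS) pair so the set carries an exact van't Hoff line as
#' ground truth.
#'
#' @param config a [SimulationConfig-class] whose `thermo` block is set.
#' @param temperaturesK temperatures to simulate (default: the design's).
#' @return named list of [TitrationSeries-class], one per temperature.
#' @export
simulateTemperatureSet <- function(config, temperaturesK = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!length(config@thermo))
    stop("simulateTemperatureSet requires the thermo block (dH, dS)")
  if (is.null(temperaturesK)) temperaturesK <- config@temperaturesK
  if (any(temperaturesK <= 0)) stop("temperature must be positive kelvin")
  out <- lapply(temperaturesK, function(Tk)
    simulateTitration(config, temperatureK = Tk))
  names(out) <- format(temperaturesK)
  out
}

#' Simulate per-concentration absorbance spectra
#'
#' Beer-Lambert bands for the configured acceptor:
#' `A(lambda, c) = epsMax * gaussian(lambda) * c * pathlength`. Used for
#' inner-filter and spectral-overlap fixtures.
#'
#' @param config a [SimulationConfig-class] with `acceptorBand` set.
#' @param concsM concentrations, M (default: the design concentrations).
#' @param pathlengthCm cuvette path length, cm.
#' @return list of absorbance [Spectrum-class], one per concentration.
#' @export
simulateAbsorbance <- function(config, concsM = NULL, pathlengthCm = 1) {
  stopifnot(is(config, "SimulationConfig"))
  if (!length(config@acceptorBand))
    stop("simulateAbsorbance requires the acceptorBand block")
  if (is.null(concsM)) concsM <- config@concsM
  if (any(concsM < 0)) stop("negative concentration")
  b <- config@acceptorBand
  shape <- gaussianBand(config@gridNm, b$centerNm, b$widthNm, b$epsMax)
  lapply(concsM, function(cc)
    Spectrum(config@gridNm, shape * cc * pathlengthCm,
             kind = "absorbance",
             label = sprintf("simulated acceptor, %.6g M", cc)))
}
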