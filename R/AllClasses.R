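#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata isEmpty
#' @importFrom stats lm coef approx median rnorm setNames qnorm
NULL

.SPECTRUM_KINDS <- c("emission", "absorbance", "synchronous")

#' Spectrum: a sampled optical trace
#'
#' A single spectrum on a strictly increasing wavelength grid. Holds either
#' fluorescence emission intensity (arbitrary units), absorbance
#' (dimensionless, or molar extinction in M^-1 cm^-1 after
#' [molarExtinction()]), or a synchronous-scan trace.
#'
#' @slot kind scan type, one of `"emission"`, `"absorbance"`, `"synchronous"`.
#' @slot wavelengthsNm strictly increasing wavelength grid in nm (>= 2 points).
#' @slot values one value per grid point; finite; absorbance must be >= 0.
#' @slot label free-text description.
#'
#' @seealso [Spectrum()] for construction, [intensityAt()], [peakPosition()],
#'   [subtractBackground()]
#' @export
setClass("Spectrum",
  slots = c(
    kind = "character",
    wavelengthsNm = "numeric",
    values = "numeric",
    label = "character"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.SPECTRUM_KINDS, collapse = ", ")))
  w <- object@wavelengthsNm
  v <- object@values
  if (length(w) < 2L)
    msg <- c(msg, "wavelength grid needs at least 2 points")
  if (anyNA(w) || any(!is.finite(w)))
    msg <- c(msg, "wavelengths must be finite")
  if (length(w) >= 2L && any(diff(w) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(v) != length(w))
    msg <- c(msg, "values and wavelengths must have equal length")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (identical(object@kind, "absorbance") && length(v) && any(v < 0))
    msg <- c(msg, "absorbance values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Titration series of spectra
#'
#' A `TitrationSeries` holds one spectrum per quencher concentration at a
#' single temperature, all sharing one wavelength grid. It extends
#' [SummarizedExperiment::SummarizedExperiment]: the `"signal"` assay is a
#' wavelength-by-concentration matrix, `rowData()` carries the wavelength
#' grid (`wavelength_nm`) and `colData()` the quencher concentrations
#' (`quencher_conc_M`). Experimental metadata live in dedicated slots.
#'
#' The first concentration may be 0; that column defines the unquenched
#' reference intensity F0 used by [sternVolmerFit()] and [doubleLogFit()].
#'
#' @slot temperatureK reaction temperature in kelvin.
#' @slot excitationNm excitation wavelength in nm (synchronous scans store
#'   the starting excitation wavelength of the scan).
#' @slot fluorophoreConcM fluorophore (protein) concentration in mol/L.
#' @slot competitor empty list, or `list(name=, concM=)` when a site-probe
#'   competitor was co-incubated.
#' @slot corrected `TRUE` once inner-filter correction has been applied.
#' @slot scanKind `"emission"` or `"synchronous"`.
#' @slot scanOffsetNm wavelength offset of a synchronous scan
#'   (`NA` for emission scans).
#'
#' @seealso [TitrationSeries()], [loadTitration()], [simulateTitration()]
#' @export
setClass("TitrationSeries",
  contains = "SummarizedExperiment",
  slots = c(
    temperatureK = "numeric",
    excitationNm = "numeric",
    fluorophoreConcM = "numeric",
    competitor = "list",
    corrected = "logical",
    scanKind = "character",
    scanOffsetNm = "numeric"
  ),
  prototype = prototype(
    temperatureK = NA_real_,
    excitationNm = NA_real_,
    fluorophoreConcM = NA_real_,
    competitor = list(),
    corrected = FALSE,
    scanKind = "emission",
    scanOffsetNm = NA_real_
  )
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (!"signal" %in% assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  if (!"wavelength_nm" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'wavelength_nm' is required")
  if (!"quencher_conc_M" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'quencher_conc_M' is required")
  if (length(msg)) return(msg)
  w <- rowData(object)$wavelength_nm
  if (length(w) < 2L || any(diff(w) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing with >= 2 points")
  q <- colData(object)$quencher_conc_M
  if (length(q) < 1L || anyNA(q) || any(q < 0))
    msg <- c(msg, "quencher concentrations must be non-negative")
  if (length(q) >= 2L && any(diff(q) <= 0))
    msg <- c(msg, "quencher concentrations must be strictly increasing")
  if (length(object@temperatureK) != 1L ||
      (!is.na(object@temperatureK) && object@temperatureK <= 0))
    msg <- c(msg, "temperatureK must be a positive scalar")
  if (!object@scanKind %in% c("emission", "synchronous"))
    msg <- c(msg, "scanKind must be 'emission' or 'synchronous'")
  if (length(object@competitor) &&
      !all(c("name", "concM") %in% names(object@competitor)))
    msg <- c(msg, "competitor must be empty or list(name=, concM=)")
  if (length(msg)) msg else TRUE
})

# ---- fit / result containers -------------------------------------------

#' Stern-Volmer fit result
#'
#' Output of [sternVolmerFit()]: the Stern-Volmer quenching constant K_sv
#' (slope of F0/F versus quencher concentration), the bimolecular quenching
#' rate k_q = K_sv / tau0, and regression diagnostics. The regression uses a
#' free intercept; `interceptF0F` should be close to the theoretical value 1.
#'
#' @slot KsvM Stern-Volmer constant, M^-1.
#' @slot KsvSeM standard error of K_sv, M^-1.
#' @slot kqMs bimolecular quenching rate constant, M^-1 s^-1 (= KsvM / tau0S).
#' @slot tau0S unquenched fluorophore lifetime used, s.
#' @slot interceptF0F fitted intercept of the F0/F line (theory: 1).
#' @slot rSquared coefficient of determination.
#' @slot temperatureK temperature of the underlying series.
#' @slot nPoints number of concentrations used.
#' @slot conclusive `FALSE` when the fitted K_sv is not positive.
#' @export
setClass("QuenchFit",
  slots = c(
    KsvM = "numeric", KsvSeM = "numeric", kqMs = "numeric", tau0S = "numeric",
    interceptF0F = "numeric", rSquared = "numeric", temperatureK = "numeric",
    nPoints = "integer", conclusive = "logical"
  )
)

setValidity("QuenchFit", function(object) {
  msg <- character()
  if (object@tau0S <= 0) msg <- c(msg, "tau0S must be positive")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (abs(object@kqMs - object@KsvM / object@tau0S) >
      1e-9 * max(1, abs(object@kqMs)))
    msg <- c(msg, "kqMs must equal KsvM / tau0S")
  if (object@conclusive && object@KsvM <= 0)
    msg <- c(msg, "a conclusive fit requires KsvM > 0")
  if (length(msg)) msg else TRUE
})

#' Quenching mechanism call
#'
#' Output of [classifyMechanism()]. `label` is one of `"static"`,
#' `"dynamic"`, `"static_dominant_ambiguous"` or `"inconclusive"`; see
#' [classifyMechanism()] for the decision rules.
#'
#' @slot label mechanism classification.
#' @slot ksvTrend temperature trend of K_sv: `"decreasing"`, `"increasing"`
#'   or `"flat"` (or `"mixed"` when not monotone).
#' @slot kqExceedsDiffusionLimit `TRUE` if any k_q exceeds the
#'   diffusion-controlled limit.
#' @slot evidence human-readable account of the decision.
#' @export
setClass("MechanismCall",
  slots = c(
    label = "character", ksvTrend = "character",
    kqExceedsDiffusionLimit = "logical", evidence = "character"
  )
)

setValidity("MechanismCall", function(object) {
  msg <- character()
  labs <- c("static", "dynamic", "static_dominant_ambiguous", "inconclusive")
  if (!object@label %in% labs)
    msg <- c(msg, sprintf("label must be one of %s", paste(labs, collapse = ", ")))
  if (!object@ksvTrend %in% c("decreasing", "increasing", "flat", "mixed"))
    msg <- c(msg, "invalid ksvTrend")
  if (object@label == "static" && object@ksvTrend != "decreasing")
    msg <- c(msg, "static call requires a decreasing K_sv trend")
  if (object@label == "dynamic" &&
      (object@ksvTrend != "increasing" || object@kqExceedsDiffusionLimit))
    msg <- c(msg, "dynamic call requires increasing K_sv and k_q below the diffusion limit")
  if (length(msg)) msg else TRUE
})

#' Double-logarithmic binding fit result
#'
#' Output of [doubleLogFit()]: apparent binding constant K_a (M^-1) and
#' number of binding sites n from the regression of log10((F0-F)/F) on
#' log10 of quencher concentration. The K_a uncertainty is multiplicative:
#' `geomErrorFactor = 10^SE(intercept)`, read as "times/divide".
#'
#' @slot KaM binding constant, M^-1.
#' @slot geomErrorFactor multiplicative (x/÷) uncertainty factor on K_a, >= 1.
#' @slot nSites number of binding sites (slope).
#' @slot nSitesSe standard error of nSites.
#' @slot rSquared coefficient of determination.
#' @slot temperatureK temperature of the underlying series.
#' @slot competitor competitor name, or `""` when none.
#' @slot nPoints number of usable concentrations.
#' @export
setClass("BindingFit",
  slots = c(
    KaM = "numeric", geomErrorFactor = "numeric",
    nSites = "numeric", nSitesSe = "numeric",
    rSquared = "numeric", temperatureK = "numeric",
    competitor = "character", nPoints = "integer"
  )
)

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@KaM <= 0) msg <- c(msg, "KaM must be positive")
  if (object@geomErrorFactor < 1) msg <- c(msg, "geomErrorFactor must be >= 1")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Site-probe displacement result
#'
#' Output of [displacementAnalysis()]: fold change of the binding constant
#' on co-incubation with a site probe, and the competitive / cooperative /
#' neutral call.
#'
#' @slot KaWithoutM binding constant without competitor, M^-1.
#' @slot KaWithM binding constant with competitor, M^-1.
#' @slot foldChange `KaWithoutM / KaWithM`.
#' @slot foldChangeRounded fold change rounded to 2 decimals.
#' @slot foldChangeNearestInt fold change rounded to the nearest integer.
#' @slot mode `"competitive"`, `"cooperative"` or `"neutral"`.
#' @slot competitor site-probe name.
#' @slot temperatureK shared temperature of both fits.
#' @slot threshold fold-change threshold used for the call.
#' @export
setClass("DisplacementResult",
  slots = c(
    KaWithoutM = "numeric", KaWithM = "numeric",
    foldChange = "numeric", foldChangeRounded = "numeric",
    foldChangeNearestInt = "numeric", mode = "character",
    competitor = "character", temperatureK = "numeric", threshold = "numeric"
  )
)

setValidity("DisplacementResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("competitive", "cooperative", "neutral"))
    msg <- c(msg, "invalid mode")
  th <- object@threshold
  if (object@mode == "competitive" && !(object@foldChange > th))
    msg <- c(msg, "competitive requires foldChange > threshold")
  if (object@mode == "cooperative" && !(object@foldChange < 1 / th))
    msg <- c(msg, "cooperative requires foldChange < 1/threshold")
  if (length(msg)) msg else TRUE
})

#' Van't Hoff thermodynamic result
#'
#' Output of [vantHoff()]: binding enthalpy and entropy from the regression
#' of ln K_a on 1/T, Gibbs free energy at each requested temperature from
#' dG = dH - T*dS (the primary route), the -RT ln K_a diagnostic values,
#' and the intermolecular-force classification from the sign pattern of
#' (dH, dS).
#'
#' @slot dHkJmol binding enthalpy, kJ mol^-1.
#' @slot dSJmolK binding entropy, J mol^-1 K^-1.
#' @slot dGkJmolByT Gibbs energy per temperature via dH - T*dS, kJ mol^-1
#'   (names are temperatures in K).
#' @slot dGfromKaByT diagnostic Gibbs energy per temperature via
#'   -RT ln K_a, kJ mol^-1.
#' @slot rSquared r-squared of the van't Hoff line.
#' @slot forceLabel one of `"hydrophobic"`, `"electrostatic_ionic"`,
#'   `"hbond_vdw"`, `"nonspontaneous"`.
#' @slot spontaneousByT logical per temperature: dG(T) < 0.
#' @slot minimalDesign `TRUE` when only two temperatures were supplied
#'   (the line is exact by construction).
#' @export
setClass("ThermoResult",
  slots = c(
    dHkJmol = "numeric", dSJmolK = "numeric",
    dGkJmolByT = "numeric", dGfromKaByT = "numeric",
    rSquared = "numeric", forceLabel = "character",
    spontaneousByT = "logical", minimalDesign = "logical"
  )
)

setValidity("ThermoResult", function(object) {
  msg <- character()
  labs <- c("hydrophobic", "electrostatic_ionic", "hbond_vdw", "nonspontaneous")
  if (!object@forceLabel %in% labs)
    msg <- c(msg, "invalid forceLabel")
  Tk <- as.numeric(names(object@dGkJmolByT))
  if (length(Tk)) {
    expected <- object@dHkJmol - Tk * object@dSJmolK / 1000
    if (any(abs(object@dGkJmolByT - expected) > 1e-9 * pmax(1, abs(expected))))
      msg <- c(msg, "dGkJmolByT must equal dH - T*dS/1000")
    if (!identical(unname(object@spontaneousByT),
                   unname(object@dGkJmolByT < 0)))
      msg <- c(msg, "spontaneousByT must mirror dG(T) < 0")
  }
  if (length(msg)) msg else TRUE
})

#' FRET analysis result
#'
#' Output of [fretAnalysis()]: transfer efficiency, spectral overlap
#' integral, Forster radius, donor-acceptor distance and validity checks.
#'
#' @slot efficiencyE transfer efficiency, in (0, 1).
#' @slot JMcmNm4 spectral overlap integral, M^-1 cm^-1 nm^4.
#' @slot R0Nm Forster radius, nm.
#' @slot rNm donor-acceptor distance, nm.
#' @slot kappa2 dipole orientation factor used.
#' @slot phiD donor quantum yield used.
#' @slot etaInv4 the eta^-4 refractive-index factor used.
#' @slot windowNm integration window `[i, j]` in nm.
#' @slot validRange `TRUE` if 0.5 R0 < r < 1.5 R0.
#' @slot within10nm `TRUE` if r < 10 nm.
#' @export
setClass("FretResult",
  slots = c(
    efficiencyE = "numeric", JMcmNm4 = "numeric", R0Nm = "numeric",
    rNm = "numeric", kappa2 = "numeric", phiD = "numeric",
    etaInv4 = "numeric", windowNm = "numeric",
    validRange = "logical", within10nm = "logical"
  )
)

setValidity("FretResult", function(object) {
  msg <- character()
  if (object@efficiencyE <= 0 || object@efficiencyE >= 1)
    msg <- c(msg, "efficiencyE must lie in (0, 1)")
  if (object@JMcmNm4 < 0) msg <- c(msg, "JMcmNm4 must be >= 0")
  if (object@R0Nm <= 0 || object@rNm <= 0)
    msg <- c(msg, "R0Nm and rNm must be positive")
  E <- object@R0Nm^6 / (object@R0Nm^6 + object@rNm^6)
  if (abs(E - object@efficiencyE) > 1e-9 * max(1, abs(E)))
    msg <- c(msg, "efficiencyE and rNm must satisfy E = R0^6/(R0^6 + r^6)")
  if (length(msg)) msg else TRUE
})

#' Synchronous-scan peak-shift result
#'
#' Output of [synchronousShift()]: the peak wavelength per quencher
#' concentration for a synchronous scan at a fixed offset, the net shift at
#' the top concentration relative to the unquenched trace (negative =
#' blueshift), and its classification.
#'
#' @slot offsetNm scan offset (15 nm reports tyrosine, 60 nm tryptophan).
#' @slot peakNmByConc peak wavelength per concentration (names are
#'   concentrations in M).
#' @slot shiftNm signed net shift, nm.
#' @slot direction `"blueshift"`, `"redshift"` or `"none"`.
#' @export
setClass("PeakShiftResult",
  slots = c(
    offsetNm = "numeric", peakNmByConc = "numeric",
    shiftNm = "numeric", direction = "character"
  )
)

setValidity("PeakShiftResult", function(object) {
  msg <- character()
  if (!object@direction %in% c("blueshift", "redshift", "none"))
    msg <- c(msg, "invalid direction")
  p <- object@peakNmByConc
  if (length(p) >= 2L) {
    expected <- unname(p[length(p)] - p[1L])
    if (abs(object@shiftNm - expected) > 1e-9)
      msg <- c(msg, "shiftNm must equal peak(top conc) - peak(zero conc)")
  }
  if (object@direction == "blueshift" && object@shiftNm >= 0)
    msg <- c(msg, "blueshift requires shiftNm < 0")
  if (object@direction == "redshift" && object@shiftNm <= 0)
    msg <- c(msg, "redshift requires shiftNm > 0")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the forward titration simulator; see [simulationConfig()].
#'
#' @slot quenchingModel `"stern_volmer_linear"`, `"hill_binding"` or
#'   `"combined"`.
#' @slot KsvM Stern-Volmer constant for the linear/combined model, M^-1.
#' @slot KaM binding constant for the hill/combined model, M^-1.
#' @slot nSites Hill exponent (number of binding sites).
#' @slot thermo empty list or `list(dH_J_mol=, dS_J_mol_K=)` to derive
#'   K_a(T) from the van't Hoff relation.
#' @slot band emission band `list(centerNm=, widthNm=, amplitude=)`.
#' @slot bandDriftNmPerM linear drift of the band center with quencher
#'   concentration, nm per M (for synchronous-shift fixtures).
#' @slot acceptorBand empty list or acceptor extinction band
#'   `list(centerNm=, widthNm=, epsMax=)` with epsMax in M^-1 cm^-1.
#' @slot noiseRel multiplicative Gaussian noise sigma (relative).
#' @slot seed integer RNG seed.
#' @slot concsM quencher concentrations, M.
#' @slot temperaturesK design temperatures, K.
#' @slot gridNm wavelength grid, nm.
#' @slot excitationNm excitation wavelength, nm.
#' @slot fluorophoreConcM fluorophore concentration, M.
#' @slot scanKind `"emission"` or `"synchronous"`.
#' @slot scanOffsetNm synchronous-scan offset (NA for emission).
#' @export
setClass("SimulationConfig",
  slots = c(
    quenchingModel = "character",
    KsvM = "numeric", KaM = "numeric", nSites = "numeric",
    thermo = "list", band = "list", bandDriftNmPerM = "numeric",
    acceptorBand = "list", noiseRel = "numeric", seed = "integer",
    concsM = "numeric", temperaturesK = "numeric", gridNm = "numeric",
    excitationNm = "numeric", fluorophoreConcM = "numeric",
    scanKind = "character", scanOffsetNm = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!object@quenchingModel %in%
        c("stern_volmer_linear", "hill_binding", "combined"))
    msg <- c(msg, "unknown quenching model")
  if (object@quenchingModel %in% c("stern_volmer_linear", "combined") &&
      (is.na(object@KsvM) || object@KsvM <= 0))
    msg <- c(msg, "KsvM must be positive for the linear/combined model")
  if (object@quenchingModel %in% c("hill_binding", "combined") &&
      length(object@thermo) == 0L &&
      (is.na(object@KaM) || object@KaM <= 0))
    msg <- c(msg, "KaM must be positive for the hill/combined model")
  if (object@quenchingModel %in% c("hill_binding", "combined") &&
      (is.na(object@nSites) || object@nSites <= 0))
    msg <- c(msg, "nSites must be positive")
  if (object@noiseRel < 0) msg <- c(msg, "noiseRel must be >= 0")
  if (anyNA(object@concsM) || any(object@concsM < 0) ||
      (length(object@concsM) > 1 && any(diff(object@concsM) <= 0)))
    msg <- c(msg, "concsM must be non-negative and strictly increasing")
  if (any(object@temperaturesK <= 0))
    msg <- c(msg, "temperaturesK must be positive")
  if (length(object@gridNm) < 2L || any(diff(object@gridNm) <= 0))
    msg <- c(msg, "gridNm must be strictly increasing with >= 2 points")
  if (length(object@thermo) &&
      !all(c("dH_J_mol", "dS_J_mol_K") %in% names(object@thermo)))
    msg <- c(msg, "thermo must be empty or list(dH_J_mol=, dS_J_mol_K=)")
  if (length(msg)) msg else TRUE
})
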