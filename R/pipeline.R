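#' Run the full binding-analysis pipeline
#'
#' Orchestrates the stages of a ligand-protein fluorescence study:
#' optional inner-filter correction, Stern-Volmer quenching per
#' temperature, mechanism classification, double-log binding fits, van't
#' Hoff thermodynamics with force classification, FRET distance
#' estimation, site-probe displacement, and synchronous-scan peak shifts.
#' Stages whose inputs are absent are skipped with a logged message,
#' never silently defaulted; a stage that errors aborts with a
#' stage-labelled message after writing a partial report (when
#' `outputDir` is set) carrying a `failed_stage` marker.
#'
#' The orchestration adds nothing numeric: every value in the report is
#' identical to calling the stage function directly on the same inputs.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{series}{named list, temperature (K) -> [TitrationSeries-class]
#'       or `list(csv=, meta=)` paths — the no-competitor titrations.}
#'     \item{competitorSeries}{optional named list, competitor name ->
#'       series (same forms), for displacement analysis at the reference
#'       temperature.}
#'     \item{synchronousSeries}{optional named list, offset ("15"/"60") ->
#'       synchronous series.}
#'     \item{fret}{optional list: `acceptorAbsorbance` ([Spectrum-class] or
#'       CSV path with columns wavelength_nm, value), `acceptorConcM`, and
#'       either `E` or both `F` and `F0`.}
#'     \item{emissionNm, tau0S, diffusionLimit, displacementThreshold,
#'       kappa2, phiD, etaInv4, windowNm}{stage constants; defaults 340,
#'       6.2e-9, 2e10, 1.5, 0.476, 0.15, 0.3139, c(285, 450).}
#'     \item{outputDir}{optional; report JSON and summary CSVs are written
#'       there.}
#'   }
#' @param verbose log stage progress to stderr.
#' @return the analysis report: a nested list with elements `quenching`,
#'   `mechanism`, `binding`, `thermodynamics`, `fret`, `displacement`,
#'   `peakShifts`, `skipped`, `provenance`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  cfg <- .pipelineDefaults(config)
  log <- function(stage, msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  report <- list(quenching = NULL, mechanism = NULL, binding = NULL,
                 thermodynamics = NULL, fret = NULL, displacement = NULL,
                 peakShifts = NULL, skipped = character(),
                 provenance = list(package = "QuenchBind",
                                   version = as.character(
                                     utils::packageVersion("QuenchBind")),
                                   timestamp = format(Sys.time(),
                                                      tz = "UTC")))
  fail <- function(stage, e) {
    report$provenance$failed_stage <- stage
    .writeReport(report, cfg$outputDir)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    log(name, "running")
    tryCatch(expr, error = function(e) fail(name, e))
  }

  if (is.null(cfg$series) || !length(cfg$series))
    stop("config must supply at least one titration series")
  series <- stage("load", lapply(cfg$series, .resolveSeries))

  qfits <- stage("quenching", lapply(series, sternVolmerFit,
                                     emissionNm = cfg$emissionNm,
                                     tau0S = cfg$tau0S))
  report$quenching <- lapply(qfits, .quenchFitAsList)

  if (length(qfits) >= 2L) {
    mech <- stage("mechanism",
                  classifyMechanism(qfits,
                                    diffusionLimit = cfg$diffusionLimit))
    report$mechanism <- list(label = mech@label, ksvTrend = mech@ksvTrend,
                             kqExceedsDiffusionLimit =
                               mech@kqExceedsDiffusionLimit,
                             evidence = mech@evidence)
  } else {
    log("mechanism", "skipped: needs >= 2 temperatures")
    report$skipped <- c(report$skipped, "mechanism")
  }

  bfits <- stage("binding", lapply(series, doubleLogFit,
                                   emissionNm = cfg$emissionNm))
  report$binding <- lapply(bfits, .bindingFitAsList)

  if (length(bfits) >= 2L) {
    thermo <- stage("thermodynamics", vantHoff(bfits))
    report$thermodynamics <- .thermoAsList(thermo)
  } else {
    log("thermodynamics", "skipped: needs >= 2 temperatures")
    report$skipped <- c(report$skipped, "thermodynamics")
  }

  if (!is.null(cfg$fret)) {
    fr <- stage("fret", .runFretStage(cfg, series))
    report$fret <- .fretAsList(fr)
  } else {
    log("fret", "skipped: no FRET inputs")
    report$skipped <- c(report$skipped, "fret")
  }

  if (!is.null(cfg$competitorSeries) && length(cfg$competitorSeries)) {
    disp <- stage("displacement", {
      lapply(names(cfg$competitorSeries), function(nm) {
        cs <- .resolveSeries(cfg$competitorSeries[[nm]])
        if (!length(competitorInfo(cs)))
          cs@competitor <- list(name = nm, concM = NA_real_)
        fitWith <- doubleLogFit(cs, emissionNm = cfg$emissionNm)
        ref <- bfits[[which(vapply(bfits, function(b)
          isTRUE(all.equal(b@temperatureK, temperatureK(cs))),
          logical(1)))[1L]]]
        displacementAnalysis(ref, fitWith,
                             threshold = cfg$displacementThreshold)
      })
    })
    names(disp) <- names(cfg$competitorSeries)
    report$displacement <- lapply(disp, .displacementAsList)
  } else {
    log("displacement", "skipped: no competitor series")
    report$skipped <- c(report$skipped, "displacement")
  }

  if (!is.null(cfg$synchronousSeries) && length(cfg$synchronousSeries)) {
    shifts <- stage("synchronous", {
      lapply(names(cfg$synchronousSeries), function(off) {
        ss <- .resolveSeries(cfg$synchronousSeries[[off]])
        synchronousShift(ss, offsetNm = as.numeric(off))
      })
    })
    names(shifts) <- names(cfg$synchronousSeries)
    report$peakShifts <- lapply(shifts, function(p)
      list(offset_nm = p@offsetNm,
           peak_nm_by_conc = as.list(p@peakNmByConc),
           shift_nm = p@shiftNm, direction = p@direction))
  } else {
    log("synchronous", "skipped: no synchronous series")
    report$skipped <- c(report$skipped, "synchronous")
  }

  .writeReport(report, cfg$outputDir)
  report
}

.pipelineDefaults <- function(config) {
  defaults <- list(emissionNm = 340, tau0S = 6.2e-9, diffusionLimit = 2e10,
                   displacementThreshold = 1.5, kappa2 = 0.476,
                   phiD = 0.15, etaInv4 = 0.3139, windowNm = c(285, 450),
                   outputDir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (any(c(config$emissionNm, config$tau0S, config$diffusionLimit,
            config$displacementThreshold, config$kappa2, config$phiD,
            config$etaInv4) <= 0))
    stop("all pipeline constants must be positive")
  config
}

.resolveSeries <- function(x) {
  if (is(x, "TitrationSeries")) return(x)
  if (is.list(x) && !is.null(x$csv) && !is.null(x$meta))
    return(loadTitration(x$csv, x$meta))
  stop("series entries must be TitrationSeries objects or list(csv=, meta=)")
}

.resolveSpectrum <- function(x, kind) {
  if (is(x, "Spectrum")) return(x)
  if (is.character(x) && length(x) == 1L) {
    tab <- utils::read.csv(x, check.names = FALSE)
    if (!all(c("wavelength_nm", "value") %in% colnames(tab)))
      stop("spectrum CSV needs columns 'wavelength_nm' and 'value'")
    return(Spectrum(tab$wavelength_nm, tab$value, kind = kind))
  }
  stop("expected a Spectrum or a CSV path")
}

.runFretStage <- function(cfg, series) {
  fr <- cfg$fret
  if (is.null(fr$acceptorAbsorbance) || is.null(fr$acceptorConcM))
    stop("fret config needs acceptorAbsorbance and acceptorConcM")
  donor <- if (!is.null(fr$donorEmission))
    .resolveSpectrum(fr$donorEmission, "emission")
  else getSpectrum(series[[1L]], 1L)   # unquenched trace of the first series
  fretAnalysis(donor,
               .resolveSpectrum(fr$acceptorAbsorbance, "absorbance"),
               acceptorConcM = fr$acceptorConcM,
               F = fr$F, F0 = fr$F0, E = fr$E,
               emissionNm = cfg$emissionNm,
               kappa2 = cfg$kappa2, phiD = cfg$phiD,
               etaInv4 = cfg$etaInv4, windowNm = cfg$windowNm)
}

.quenchFitAsList <- function(f)
  list(Ksv_M = f@KsvM, Ksv_se_M = f@KsvSeM, kq_M_s = f@kqMs,
       tau0_s = f@tau0S, intercept = f@interceptF0F,
       r_squared = f@rSquared, temperature_K = f@temperatureK,
       n_points = f@nPoints, conclusive = f@conclusive)

.bindingFitAsList <- function(f)
  list(Ka_M = f@KaM, geom_error_factor = f@geomErrorFactor,
       n_sites = f@nSites, n_sites_se = f@nSitesSe,
       r_squared = f@rSquared, temperature_K = f@temperatureK,
       competitor = f@competitor, n_points = f@nPoints)

.thermoAsList <- function(t)
  list(dH_kJ_mol = t@dHkJmol, dS_J_mol_K = t@dSJmolK,
       dG_kJ_mol_by_T = as.list(t@dGkJmolByT),
       dG_from_Ka_by_T = as.list(t@dGfromKaByT),
       r_squared = t@rSquared, force_label = t@forceLabel,
       spontaneous_by_T = as.list(t@spontaneousByT),
       minimal_design = t@minimalDesign)

.fretAsList <- function(f)
  list(efficiency_E = f@efficiencyE, J_M_cm_nm4 = f@JMcmNm4,
       R0_nm = f@R0Nm, r_nm = f@rNm, kappa2 = f@kappa2, phi_D = f@phiD,
       eta_inv4 = f@etaInv4, window_nm = f@windowNm,
       valid_range = f@validRange, within_10nm = f@within10nm)

.displacementAsList <- function(d)
  list(Ka_without_M = d@KaWithoutM, Ka_with_M = d@KaWithM,
       fold_change = d@foldChange,
       fold_change_rounded = d@foldChangeRounded,
       fold_change_nearest_int = d@foldChangeNearestInt,
       mode = d@mode, competitor = d@competitor,
       temperature_K = d@temperatureK, threshold = d@threshold)

.writeReport <- function(report, outputDir) {
  if (is.null(outputDir)) return(invisible(NULL))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(report$quenching)) {
    q <- do.call(rbind, lapply(names(report$quenching), function(Tn)
      data.frame(temperature_K = as.numeric(Tn),
                 Ksv_M = report$quenching[[Tn]]$Ksv_M,
                 kq_M_s = report$quenching[[Tn]]$kq_M_s,
                 r_squared = report$quenching[[Tn]]$r_squared)))
    utils::write.csv(q, file.path(outputDir, "stern_volmer.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$binding)) {
    b <- do.call(rbind, lapply(names(report$binding), function(Tn)
      data.frame(temperature_K = as.numeric(Tn),
                 Ka_M = report$binding[[Tn]]$Ka_M,
                 n_sites = report$binding[[Tn]]$n_sites,
                 r_squared = report$binding[[Tn]]$r_squared)))
    utils::write.csv(b, file.path(outputDir, "binding.csv"),
                     row.names = FALSE)
  }
  invisible(NULL)
}
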