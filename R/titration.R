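#' Construct a TitrationSeries
#'
#' @param spectra list of [Spectrum-class] objects sharing one wavelength
#'   grid (one per concentration), or a wavelength-by-concentration signal
#'   matrix.
#' @param quencherConcsM quencher concentrations in mol/L, non-negative and
#'   strictly increasing; the first may be 0 (the unquenched F0 trace).
#' @param temperatureK temperature, K.
#' @param wavelengthsNm wavelength grid, required when `spectra` is a matrix.
#' @param excitationNm excitation wavelength, nm.
#' @param fluorophoreConcM fluorophore concentration, M.
#' @param competitor `NULL` or `list(name=, concM=)`.
#' @param corrected has inner-filter correction been applied already?
#' @param scanKind `"emission"` or `"synchronous"`.
#' @param scanOffsetNm offset of a synchronous scan, nm.
#' @return A [TitrationSeries-class].
#' @examples
#' grid <- 285:450
#' sp <- lapply(c(1, 0.8, 0.6), function(f)
#'   Spectrum(grid, f * gaussianBand(grid, 340, 15, 1000)))
#' ts <- TitrationSeries(sp, quencherConcsM = c(0, 2e-5, 8e-5),
#'                       temperatureK = 310)
#' intensityAt(ts, 340)
#' @export
TitrationSeries <- function(spectra, quencherConcsM, temperatureK,
                            wavelengthsNm = NULL,
                            excitationNm = 280, fluorophoreConcM = 2e-6,
                            competitor = NULL, corrected = FALSE,
                            scanKind = c("emission", "synchronous"),
                            scanOffsetNm = NA_real_) {
  scanKind <- match.arg(scanKind)
  quencherConcsM <- as.numeric(quencherConcsM)
  if (is.list(spectra)) {
    if (length(spectra) != length(quencherConcsM))
      stop(sprintf("got %d spectra for %d concentrations",
                   length(spectra), length(quencherConcsM)))
    grids <- lapply(spectra, wavelengths)
    if (length(spectra) > 1L &&
        !all(vapply(grids[-1L], identical, logical(1), grids[[1L]])))
      stop("all spectra in a series must share one wavelength grid")
    wavelengthsNm <- grids[[1L]]
    mat <- vapply(spectra, intensities, numeric(length(wavelengthsNm)))
  } else {
    mat <- as.matrix(spectra)
    if (is.null(wavelengthsNm))
      stop("wavelengthsNm is required when spectra is a matrix")
    if (nrow(mat) != length(wavelengthsNm))
      stop("signal matrix rows must match the wavelength grid")
    if (ncol(mat) != length(quencherConcsM))
      stop(sprintf("got %d signal columns for %d concentrations",
                   ncol(mat), length(quencherConcsM)))
  }
  dimnames(mat) <- list(NULL, sprintf("c%d", seq_along(quencherConcsM)))
  se <- SummarizedExperiment(
    assays = list(signal = mat),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelengthsNm)),
    colData = DataFrame(quencher_conc_M = quencherConcsM,
                        row.names = colnames(mat))
  )
  new("TitrationSeries", se,
      temperatureK = as.numeric(temperatureK),
      excitationNm = as.numeric(excitationNm),
      fluorophoreConcM = as.numeric(fluorophoreConcM),
      competitor = if (is.null(competitor)) list() else competitor,
      corrected = isTRUE(corrected),
      scanKind = scanKind,
      scanOffsetNm = as.numeric(scanOffsetNm))
}

#' @describeIn TitrationSeries wavelength grid, nm.
#' @param x a `TitrationSeries`.
#' @export
setMethod("wavelengths", "TitrationSeries",
          function(x) rowData(x)$wavelength_nm)

#' @describeIn TitrationSeries quencher concentrations, M.
#' @export
setMethod("quencherConcs", "TitrationSeries",
          function(x) colData(x)$quencher_conc_M)

#' @describeIn TitrationSeries temperature, K.
#' @export
setMethod("temperatureK", "TitrationSeries", function(x) x@temperatureK)

#' @describeIn TitrationSeries excitation wavelength, nm.
#' @export
setMethod("excitationNm", "TitrationSeries", function(x) x@excitationNm)

#' @describeIn TitrationSeries fluorophore concentration, M.
#' @export
setMethod("fluorophoreConc", "TitrationSeries",
          function(x) x@fluorophoreConcM)

#' @describeIn TitrationSeries competitor info (`list()` when none).
#' @export
setMethod("competitorInfo", "TitrationSeries", function(x) x@competitor)

#' @describeIn TitrationSeries has inner-filter correction been applied?
#' @export
setMethod("isCorrected", "TitrationSeries", function(x) x@corrected)

#' @describeIn TitrationSeries `"emission"` or `"synchronous"`.
#' @export
setMethod("scanKind", "TitrationSeries", function(x) x@scanKind)

#' @describeIn TitrationSeries extract the i-th trace as a [Spectrum-class].
#' @param i column (concentration) index.
#' @export
setMethod("getSpectrum", "TitrationSeries", function(x, i) {
  stopifnot(i >= 1L, i <= ncol(x))
  Spectrum(wavelengths(x), assay(x, "signal")[, i],
           kind = if (x@scanKind == "synchronous") "synchronous" else "emission",
           label = sprintf("[Q] = %.6g M", quencherConcs(x)[i]))
})

setMethod("show", "TitrationSeries", function(object) {
  q <- quencherConcs(object)
  cat(sprintf("TitrationSeries: %d spectra (%s scan), %d wavelengths\n",
              ncol(object), object@scanKind, nrow(object)))
  cat(sprintf("  [Q] %.3g-%.3g M | T = %s K | ex %s nm | corrected: %s\n",
              min(q), max(q), format(object@temperatureK),
              format(object@excitationNm), object@corrected))
  if (length(object@competitor))
    cat(sprintf("  competitor: %s (%.3g M)\n",
                object@competitor$name, object@competitor$concM))
})

#' @rdname intensityAt
#' @export
setMethod("intensityAt", "TitrationSeries", function(x, lambdaNm) {
  w <- wavelengths(x)
  out <- apply(assay(x, "signal"), 2L, function(v) .interpAt(w, v, lambdaNm))
  names(out) <- format(quencherConcs(x))
  out
})

# ---- file I/O -----------------------------------------------------------

.requireField <- function(meta, field) {
  if (is.null(meta[[field]]))
    stop(sprintf("metadata field '%s' is missing", field))
  meta[[field]]
}

.concToMolar <- function(conc, units) {
  switch(units,
         uM = conc * 1e-6,
         M = conc,
         stop(sprintf("metadata field 'units' must be 'uM' or 'M', got '%s'",
                      units)))
}

#' Read a titration series from CSV + JSON metadata
#'
#' The CSV has a `wavelength_nm` column followed by one intensity column
#' per quencher concentration, in the order of the metadata's
#' `quencher_concs`. The JSON sidecar declares `temperature_K`,
#' `excitation_nm`, `fluorophore_conc`, `quencher_concs`, `units`
#' (`"uM"` or `"M"`) and optionally `competitor`, `scan_kind`,
#' `scan_offset_nm`, `corrected`. Concentrations are converted to molar
#' internally.
#'
#' @param spectraCsvPath path to the spectra CSV.
#' @param metadataPath path to the JSON metadata sidecar.
#' @return A [TitrationSeries-class].
#' @seealso [writeTitration()]
#' @export
loadTitration <- function(spectraCsvPath, metadataPath) {
  tab <- utils::read.csv(spectraCsvPath, check.names = FALSE)
  if (!"wavelength_nm" %in% colnames(tab))
    stop("spectra CSV is missing the 'wavelength_nm' column")
  w <- tab$wavelength_nm
  if (length(w) < 2L || any(diff(w) <= 0))
    stop("column 'wavelength_nm' must be strictly increasing")
  meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  units <- .requireField(meta, "units")
  concs <- .concToMolar(as.numeric(.requireField(meta, "quencher_concs")),
                        units)
  icols <- setdiff(colnames(tab), "wavelength_nm")
  if (length(icols) != length(concs))
    stop(sprintf(
      "CSV has %d intensity columns but metadata lists %d concentrations",
      length(icols), length(concs)))
  comp <- meta$competitor
  if (!is.null(comp) && length(comp))
    comp <- list(name = .requireField(comp, "name"),
                 concM = .concToMolar(as.numeric(.requireField(comp, "conc")),
                                      units))
  else comp <- NULL
  TitrationSeries(
    as.matrix(tab[icols]),
    quencherConcsM = concs,
    wavelengthsNm = w,
    temperatureK = as.numeric(.requireField(meta, "temperature_K")),
    excitationNm = as.numeric(.requireField(meta, "excitation_nm")),
    fluorophoreConcM = .concToMolar(
      as.numeric(.requireField(meta, "fluorophore_conc")), units),
    competitor = comp,
    corrected = isTRUE(meta$corrected),
    scanKind = if (identical(meta$scan_kind, "synchronous"))
      "synchronous" else "emission",
    scanOffsetNm = if (is.null(meta$scan_offset_nm)) NA_real_
                   else as.numeric(meta$scan_offset_nm)
  )
}

#' Write a titration series to CSV + JSON metadata
#'
#' Inverse of [loadTitration()]. Concentrations are written in molar
#' (`units = "M"`) with full precision (`loadTitration()` round-trips the
#' numbers bit-identically for finite decimal inputs). Column order is
#' deterministic: `wavelength_nm`, then one `I_<i>` column per
#' concentration in metadata order.
#'
#' @param series a [TitrationSeries-class].
#' @param spectraCsvPath output CSV path.
#' @param metadataPath output JSON path.
#' @return invisibly, the two paths.
#' @export
writeTitration <- function(series, spectraCsvPath, metadataPath) {
  stopifnot(is(series, "TitrationSeries"))
  mat <- assay(series, "signal")
  tab <- data.frame(wavelength_nm = wavelengths(series), mat,
                    check.names = FALSE)
  colnames(tab) <- c("wavelength_nm",
                     sprintf("I_%d", seq_len(ncol(mat))))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   spectraCsvPath, row.names = FALSE, quote = FALSE)
  comp <- competitorInfo(series)
  meta <- list(
    temperature_K = temperatureK(series),
    excitation_nm = excitationNm(series),
    fluorophore_conc = fluorophoreConc(series),
    quencher_concs = quencherConcs(series),
    units = "M",
    competitor = if (length(comp))
      list(name = comp$name, conc = comp$concM) else NULL,
    corrected = isCorrected(series),
    scan_kind = scanKind(series),
    scan_offset_nm = if (is.na(series@scanOffsetNm)) NULL
                     else series@scanOffsetNm
  )
  jsonlite::write_json(meta, metadataPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(spectraCsvPath, metadataPath))
}

# ---- corrections --------------------------------------------------------

#' Inner-filter correction of a titration series
#'
#' Removes the attenuation of excitation and emission light by sample
#' absorbance: every observed intensity is multiplied by
#' `exp((A_ex + A_em(lambda)) / 2)`, where `A_ex` is the absorbance at the
#' excitation wavelength and `A_em(lambda)` the absorbance at each emission
#' wavelength, both for the matching quencher concentration. Since A >= 0
#' the correction never decreases an intensity.
#'
#' @param series an uncorrected [TitrationSeries-class].
#' @param absorbanceEx numeric, absorbance at the excitation wavelength,
#'   one value per concentration.
#' @param absorbanceEm list of absorbance [Spectrum-class] objects, one per
#'   concentration, interpolated onto the series grid as needed. A single
#'   `Spectrum` is recycled across concentrations.
#' @return the corrected [TitrationSeries-class] (`isCorrected()` is `TRUE`).
#' @export
innerFilterCorrect <- function(series, absorbanceEx, absorbanceEm) {
  stopifnot(is(series, "TitrationSeries"))
  if (isCorrected(series))
    stop("series is already inner-filter corrected")
  nconc <- ncol(series)
  if (length(absorbanceEx) != nconc)
    stop(sprintf("absorbanceEx has %d entries for %d concentrations",
                 length(absorbanceEx), nconc))
  if (any(absorbanceEx < 0))
    stop("negative absorbance at the excitation wavelength")
  if (is(absorbanceEm, "Spectrum"))
    absorbanceEm <- rep(list(absorbanceEm), nconc)
  if (length(absorbanceEm) != nconc)
    stop(sprintf("absorbanceEm has %d spectra for %d concentrations",
                 length(absorbanceEm), nconc))
  w <- wavelengths(series)
  mat <- assay(series, "signal")
  for (i in seq_len(nconc)) {
    sp <- absorbanceEm[[i]]
    stopifnot(is(sp, "Spectrum"))
    if (any(intensities(sp) < 0)) stop("negative emission absorbance")
    aem <- if (identical(wavelengths(sp), w)) intensities(sp)
           else vapply(w, function(l)
             .interpAt(wavelengths(sp), intensities(sp), l), numeric(1))
    mat[, i] <- mat[, i] * exp((absorbanceEx[i] + aem) / 2)
  }
  out <- series
  assay(out, "signal") <- mat
  out@corrected <- TRUE
  validObject(out)
  out
}

# ---- synchronous-scan shift ---------------------------------------------

#' Peak shift of a synchronous-fluorescence titration
#'
#' For a synchronous scan at fixed offset (15 nm probes tyrosine, 60 nm
#' tryptophan), locates the emission maximum at every quencher
#' concentration and reports the net shift of the band at the highest
#' concentration relative to the unquenched trace. Negative shifts are
#' blueshifts (residues moving into a more hydrophobic environment).
#' Shifts smaller than half a grid step are classified `"none"` —
#' sub-resolution movements are not claims.
#'
#' @param series a synchronous [TitrationSeries-class] with >= 2
#'   concentrations.
#' @param offsetNm scan offset, 15 or 60 nm.
#' @param windowNm optional search window for the peak.
#' @return A [PeakShiftResult-class].
#' @export
synchronousShift <- function(series, offsetNm, windowNm = NULL) {
  stopifnot(is(series, "TitrationSeries"))
  if (scanKind(series) != "synchronous")
    stop("series is not a synchronous scan")
  if (ncol(series) < 2L)
    stop("peak-shift analysis needs at least 2 concentrations")
  offsetNm <- as.numeric(offsetNm)
  if (!offsetNm %in% c(15, 60))
    stop("offsetNm must be 15 or 60")
  if (!is.na(series@scanOffsetNm) && series@scanOffsetNm != offsetNm)
    stop(sprintf("series was scanned at offset %g nm, not %g nm",
                 series@scanOffsetNm, offsetNm))
  peaks <- vapply(seq_len(ncol(series)), function(i)
    peakPosition(getSpectrum(series, i), windowNm), numeric(1))
  names(peaks) <- format(quencherConcs(series))
  shift <- unname(peaks[length(peaks)] - peaks[1L])
  step <- median(diff(wavelengths(series)))
  direction <- if (abs(shift) < 0.5 * step) "none"
               else if (shift < 0) "blueshift" else "redshift"
  new("PeakShiftResult", offsetNm = offsetNm, peakNmByConc = peaks,
      shiftNm = shift, direction = direction)
}

setMethod("show", "PeakShiftResult", function(object) {
  cat(sprintf("Synchronous scan (offset %g nm): shift %+.3g nm [%s]\n",
              object@offsetNm, object@shiftNm, object@direction))
})
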