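# Generics for accessors shared across the fit/result classes.

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("quencherConcs", function(x) standardGeneric("quencherConcs"))

#' @export
setGeneric("temperatureK", function(x) standardGeneric("temperatureK"))

#' @export
setGeneric("excitationNm", function(x) standardGeneric("excitationNm"))

#' @export
setGeneric("fluorophoreConc", function(x) standardGeneric("fluorophoreConc"))

#' @export
setGeneric("competitorInfo", function(x) standardGeneric("competitorInfo"))

#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))

#' @export
setGeneric("scanKind", function(x) standardGeneric("scanKind"))

#' @export
setGeneric("getSpectrum", function(x, i) standardGeneric("getSpectrum"))

#' @export
setGeneric("intensityAt", function(x, lambdaNm) standardGeneric("intensityAt"))

#' @export
setGeneric("peakPosition",
  function(x, windowNm = NULL) standardGeneric("peakPosition"))

#' @export
setGeneric("ksv", function(x) standardGeneric("ksv"))

#' @export
setGeneric("kq", function(x) standardGeneric("kq"))

#' @export
setGeneric("ka", function(x) standardGeneric("ka"))

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("deltaH", function(x) standardGeneric("deltaH"))

#' @export
setGeneric("deltaS", function(x) standardGeneric("deltaS"))

#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))

#' @export
setGeneric("forceLabel", function(x) standardGeneric("forceLabel"))

#' @export
setGeneric("mechanismLabel", function(x) standardGeneric("mechanismLabel"))
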