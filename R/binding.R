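#' Double-logarithmic binding analysis
#'
#' Fits `log10((F0 - F)/F) = log10(Ka) + n * log10([Q])` by ordinary least
#' squares over the nonzero quencher concentrations (the zero point is
#' excluded: log 0 is undefined). The slope is the number of binding sites
#' n (n ~ 1 means a single, non-cooperative site) and 10^intercept the
#' apparent binding constant K_a. Logarithms here are base 10; the van't
#' Hoff analysis ([vantHoff()]) uses natural logs — the two bases are
#' fixed and must not be mixed.
#'
#' Points where F >= F0 (no net quenching, possible at low concentrations
#' in noisy data) are excluded with a warning; at least 3 usable points
#' are required. K_a uncertainty is multiplicative —
#' `geomErrorFactor = 10^SE(intercept)`, a dimensionless x/÷ factor.
#'
#' @param series a [TitrationSeries-class] whose first concentration is 0.
#' @param emissionNm wavelength at which F and F0 are read, nm.
#' @return A [BindingFit-class].
#' @seealso [displacementAnalysis()], [vantHoff()]
#' @export
doubleLogFit <- function(series, emissionNm = 340) {
  stopifnot(is(series, "TitrationSeries"))
  q <- quencherConcs(series)
  if (q[1L] != 0)
    stop("series must contain a zero-concentration trace (defines F0)")
  if (sum(q > 0) < 3L)
    stop("double-log fit needs at least 3 nonzero concentrations")
  f <- intensityAt(series, emissionNm)
  if (any(f <= 0)) stop("non-positive fluorescence intensity")
  F0 <- f[1L]
  qn <- q[-1L]
  fn <- f[-1L]
  usable <- fn < F0
  if (any(!usable))
    warning(sprintf(
      "%d point(s) with F >= F0 excluded from the double-log fit",
      sum(!usable)))
  if (sum(usable) < 3L)
    stop("fewer than 3 usable points for the double-log fit")
  x <- log10(qn[usable])
  y <- log10((F0 - fn[usable]) / fn[usable])
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  comp <- competitorInfo(series)
  new("BindingFit",
      KaM = unname(10^coef(fit)[1L]),
      geomErrorFactor = unname(10^sm$coefficients[1L, 2L]),
      nSites = unname(coef(fit)[2L]),
      nSitesSe = unname(sm$coefficients[2L, 2L]),
      rSquared = sm$r.squared,
      temperatureK = temperatureK(series),
      competitor = if (length(comp)) comp$name else "",
      nPoints = as.integer(sum(usable)))
}

#' Site-probe competitive displacement analysis
#'
#' Compares the binding constant measured alone with the one measured
#' under co-incubation with a site probe (warfarin marks Sudlow site I,
#' ibuprofen site II). A fold decrease above `threshold` is competitive
#' binding (the probe and the ligand contend for the same pocket); a fold
#' increase beyond the reciprocal threshold is cooperative; anything in
#' between is neutral.
#'
#' @param fitWithout [BindingFit-class] without competitor.
#' @param fitWith [BindingFit-class] with the competitor present (its
#'   `competitor` field must be set); same temperature as `fitWithout`.
#' @param threshold fold-change threshold for the call (default 1.5).
#' @return A [DisplacementResult-class].
#' @examples
#' a <- new("BindingFit", KaM = 3897, geomErrorFactor = 1.49,
#'          nSites = 0.89, nSitesSe = 0.04, rSquared = 0.9874,
#'          temperatureK = 310, competitor = "", nPoints = 9L)
#' b <- new("BindingFit", KaM = 172, geomErrorFactor = 1.65,
#'          nSites = 0.63, nSitesSe = 0.03, rSquared = 0.9894,
#'          temperatureK = 310, competitor = "warfarin", nPoints = 9L)
#' displacementAnalysis(a, b)  # ~23-fold decrease: competitive
#' @export
displacementAnalysis <- function(fitWithout, fitWith, threshold = 1.5) {
  stopifnot(is(fitWithout, "BindingFit"), is(fitWith, "BindingFit"))
  if (threshold <= 1) stop("threshold must exceed 1")
  if (!isTRUE(all.equal(fitWithout@temperatureK, fitWith@temperatureK)))
    stop(sprintf("temperature mismatch: %g K vs %g K",
                 fitWithout@temperatureK, fitWith@temperatureK))
  if (!nzchar(fitWith@competitor))
    stop("fitWith must carry a competitor name")
  fold <- fitWithout@KaM / fitWith@KaM
  mode <- if (fold > threshold) "competitive"
          else if (fold < 1 / threshold) "cooperative"
          else "neutral"
  new("DisplacementResult",
      KaWithoutM = fitWithout@KaM, KaWithM = fitWith@KaM,
      foldChange = fold,
      foldChangeRounded = round(fold, 2),
      foldChangeNearestInt = round(fold),
      mode = mode, competitor = fitWith@competitor,
      temperatureK = fitWithout@temperatureK,
      threshold = threshold)
}

#' @describeIn BindingFit binding constant, M^-1.
#' @param x a `BindingFit`.
#' @export
setMethod("ka", "BindingFit", function(x) x@KaM)

#' @describeIn BindingFit number of binding sites (slope).
#' @export
setMethod("nSites", "BindingFit", function(x) x@nSites)

#' @describeIn BindingFit r-squared of the double-log line.
#' @export
setMethod("rSquared", "BindingFit", function(x) x@rSquared)

#' @describeIn BindingFit temperature of the series, K.
#' @export
setMethod("temperatureK", "BindingFit", function(x) x@temperatureK)

setMethod("show", "BindingFit", function(object) {
  cat(sprintf(
    "Double-log binding fit (T = %s K, %d points%s)\n  K_a = %.4g M^-1 (x/ %.3g) | n = %.3g +/- %.2g | r^2 = %.4f\n",
    format(object@temperatureK), object@nPoints,
    if (nzchar(object@competitor))
      paste0(", competitor: ", object@competitor) else "",
    object@KaM, object@geomErrorFactor,
    object@nSites, object@nSitesSe, object@rSquared))
})

setMethod("show", "DisplacementResult", function(object) {
  cat(sprintf(
    "Displacement by %s (T = %s K): K_a %.4g -> %.4g M^-1\n  fold change %.2f (~%d-fold): %s\n",
    object@competitor, format(object@temperatureK),
    object@KaWithoutM, object@KaWithM,
    object@foldChange, object@foldChangeNearestInt, object@mode))
})
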