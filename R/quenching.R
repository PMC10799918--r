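#' Stern-Volmer analysis of a quenching titration
#'
#' Fits `F0/F = 1 + Ksv * [Q]` by ordinary least squares with a free
#' intercept. F and F0 are read at the fixed emission wavelength of the
#' unquenched maximum (default 340 nm for serum albumin excited at
#' 280 nm), not at per-spectrum maxima, so peak drift cannot contaminate
#' the quenching ratios. The intercept is not forced to its theoretical
#' value 1; its deviation is available as a diagnostic (`interceptF0F`).
#'
#' @param series a [TitrationSeries-class] whose first concentration is 0
#'   (the F0 trace) with at least 3 nonzero concentrations.
#' @param emissionNm wavelength at which F and F0 are read, nm.
#' @param tau0S unquenched fluorophore lifetime, s (default 6.2 ns, the
#'   literature lifetime of unquenched BSA).
#' @return A [QuenchFit-class].
#' @seealso [quenchRate()], [classifyMechanism()]
#' @export
sternVolmerFit <- function(series, emissionNm = 340, tau0S = 6.2e-9) {
  stopifnot(is(series, "TitrationSeries"))
  if (tau0S <= 0) stop("tau0S must be positive")
  q <- quencherConcs(series)
  if (q[1L] != 0)
    stop("series must contain a zero-concentration trace (defines F0)")
  if (sum(q > 0) < 3L)
    stop("Stern-Volmer fit needs at least 3 nonzero concentrations")
  f <- intensityAt(series, emissionNm)
  if (any(f <= 0)) stop("non-positive fluorescence intensity")
  F0 <- f[1L]
  y <- F0 / f
  fit <- lm(y ~ q)
  # noiseless validation data fit exactly; silence summary.lm's note
  sm <- suppressWarnings(summary(fit))
  Ksv <- unname(coef(fit)[2L])
  new("QuenchFit",
      KsvM = Ksv,
      KsvSeM = unname(sm$coefficients[2L, 2L]),
      kqMs = Ksv / tau0S,
      tau0S = tau0S,
      interceptF0F = unname(coef(fit)[1L]),
      rSquared = sm$r.squared,
      temperatureK = temperatureK(series),
      nPoints = length(q),
      conclusive = Ksv > 0)
}

#' Bimolecular quenching rate constant
#'
#' `kq = Ksv / tau0`. Values far above the diffusion-controlled limit
#' (~2e10 M^-1 s^-1) indicate ground-state complex formation rather than
#' purely collisional quenching.
#'
#' @param KsvM Stern-Volmer constant, M^-1.
#' @param tau0S unquenched fluorophore lifetime, s (> 0).
#' @return quenching rate constant, M^-1 s^-1.
#' @examples
#' quenchRate(1.92e4)  # 3.097e12 M^-1 s^-1
#' @export
quenchRate <- function(KsvM, tau0S = 6.2e-9) {
  if (any(tau0S <= 0)) stop("tau0S must be positive")
  KsvM / tau0S
}

#' Static/dynamic quenching mechanism classification
#'
#' Classifies the quenching mechanism from the temperature trend of K_sv
#' and the magnitude of k_q:
#' \itemize{
#'   \item K_sv decreasing with temperature: `"static"` (heat dissociates
#'     the ground-state complex);
#'   \item K_sv increasing with all k_q at or below the diffusion limit:
#'     `"dynamic"` (collisional);
#'   \item K_sv increasing but any k_q above the limit:
#'     `"static_dominant_ambiguous"` — a collisional trend that is
#'     physically impossible to sustain, so complex formation still
#'     dominates;
#'   \item otherwise `"inconclusive"`.
#' }
#' K_sv values whose relative spread is below `flatTol` are called flat;
#' monotonicity must hold strictly across all temperature pairs, and mixed
#' orderings are inconclusive.
#'
#' @param fits list of [QuenchFit-class] at >= 2 distinct temperatures
#'   (sorted internally).
#' @param diffusionLimit diffusion-controlled rate limit, M^-1 s^-1.
#' @param flatTol relative K_sv spread below which the trend is flat.
#' @return A [MechanismCall-class].
#' @export
classifyMechanism <- function(fits, diffusionLimit = 2e10, flatTol = 0.05) {
  stopifnot(is.list(fits),
            all(vapply(fits, is, logical(1), "QuenchFit")))
  if (length(fits) < 2L)
    stop("mechanism classification needs fits at >= 2 temperatures")
  temps <- vapply(fits, function(f) f@temperatureK, numeric(1))
  if (anyDuplicated(temps)) stop("duplicate temperatures")
  ord <- order(temps)
  ksvs <- vapply(fits, function(f) f@KsvM, numeric(1))[ord]
  kqs <- vapply(fits, function(f) f@kqMs, numeric(1))[ord]
  spread <- (max(ksvs) - min(ksvs)) / mean(ksvs)
  trend <- if (spread < flatTol) "flat"
           else if (all(diff(ksvs) < 0)) "decreasing"
           else if (all(diff(ksvs) > 0)) "increasing"
           else "mixed"
  exceeds <- any(kqs > diffusionLimit)
  label <- if (trend == "decreasing") "static"
           else if (trend == "increasing" && !exceeds) "dynamic"
           else if (trend == "increasing" && exceeds)
             "static_dominant_ambiguous"
           else "inconclusive"
  evidence <- sprintf(
    paste0("K_sv %s with temperature (%s M^-1 at %s K); ",
           "max k_q = %.3g M^-1 s^-1 %s diffusion limit %.3g"),
    trend,
    paste(signif(ksvs, 4), collapse = ", "),
    paste(sort(temps), collapse = ", "),
    max(kqs), if (exceeds) "exceeds" else "within", diffusionLimit)
  new("MechanismCall", label = label, ksvTrend = trend,
      kqExceedsDiffusionLimit = exceeds, evidence = evidence)
}

#' @describeIn QuenchFit Stern-Volmer constant, M^-1.
#' @param x a `QuenchFit`.
#' @export
setMethod("ksv", "QuenchFit", function(x) x@KsvM)

#' @describeIn QuenchFit quenching rate constant, M^-1 s^-1.
#' @export
setMethod("kq", "QuenchFit", function(x) x@kqMs)

#' @describeIn QuenchFit r-squared of the Stern-Volmer line.
#' @export
setMethod("rSquared", "QuenchFit", function(x) x@rSquared)

#' @describeIn QuenchFit temperature of the series, K.
#' @export
setMethod("temperatureK", "QuenchFit", function(x) x@temperatureK)

setMethod("show", "QuenchFit", function(object) {
  cat(sprintf(
    "Stern-Volmer fit (T = %s K, %d points)\n  K_sv = %.4g +/- %.2g M^-1 | k_q = %.4g M^-1 s^-1 (tau0 = %.3g s)\n  intercept = %.4f | r^2 = %.4f%s\n",
    format(object@temperatureK), object@nPoints,
    object@KsvM, object@KsvSeM, object@kqMs, object@tau0S,
    object@interceptF0F, object@rSquared,
    if (object@conclusive) "" else " [non-positive K_sv: inconclusive]"))
})

#' @describeIn MechanismCall the mechanism label.
#' @param x a `MechanismCall`.
#' @export
setMethod("mechanismLabel", "MechanismCall", function(x) x@label)

setMethod("show", "MechanismCall", function(object) {
  cat(sprintf("Quenching mechanism: %s\n  %s\n",
              object@label, object@evidence))
})
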