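#' Molar extinction spectrum from an absorbance spectrum
#'
#' Beer-Lambert inversion: `epsilon(lambda) = A(lambda) / (c * l)` with
#' the concentration in M and the path length in cm, giving molar
#' extinction in M^-1 cm^-1.
#'
#' @param absorbance an absorbance [Spectrum-class].
#' @param concM chromophore concentration, M (> 0).
#' @param pathlengthCm cuvette path length, cm (> 0).
#' @return a [Spectrum-class] of molar extinction values (kind
#'   `"absorbance"`).
#' @export
molarExtinction <- function(absorbance, concM, pathlengthCm = 1) {
  stopifnot(is(absorbance, "Spectrum"))
  if (concM <= 0) stop("concentration must be positive")
  if (pathlengthCm <= 0) stop("path length must be positive")
  Spectrum(wavelengths(absorbance),
           intensities(absorbance) / (concM * pathlengthCm),
           kind = "absorbance",
           label = sprintf("molar extinction (%s)", absorbance@label))
}

#' Spectral overlap integral
#'
#' `J = integral(F(lambda) * eps(lambda) * lambda^4) / integral(F(lambda))`
#' over the window `[i, j]` (default 285-450 nm), evaluated by the
#' trapezoidal rule on the donor's native grid (the acceptor extinction is
#' linearly interpolated onto it when the grids differ). With extinction
#' in M^-1 cm^-1 and wavelengths in nm, J has units M^-1 cm^-1 nm^4. The
#' normalisation makes J invariant under uniform scaling of the donor
#' emission.
#'
#' @param donorEmission donor emission [Spectrum-class].
#' @param acceptorExtinction acceptor molar-extinction [Spectrum-class]
#'   (from [molarExtinction()]).
#' @param windowNm integration limits `c(i, j)`, nm; both spectra must
#'   cover the window.
#' @return overlap integral J, M^-1 cm^-1 nm^4.
#' @export
overlapIntegral <- function(donorEmission, acceptorExtinction,
                            windowNm = c(285, 450)) {
  stopifnot(is(donorEmission, "Spectrum"),
            is(acceptorExtinction, "Spectrum"),
            length(windowNm) == 2L, windowNm[1L] < windowNm[2L])
  wd <- wavelengths(donorEmission)
  wa <- wavelengths(acceptorExtinction)
  if (windowNm[1L] < wd[1L] || windowNm[2L] > wd[length(wd)])
    stop("donor emission spectrum does not cover the integration window")
  if (windowNm[1L] < wa[1L] || windowNm[2L] > wa[length(wa)])
    stop("acceptor extinction spectrum does not cover the integration window")
  sel <- wd >= windowNm[1L] & wd <= windowNm[2L]
  w <- wd[sel]
  # make the window edges exact grid points
  if (w[1L] > windowNm[1L]) w <- c(windowNm[1L], w)
  if (w[length(w)] < windowNm[2L]) w <- c(w, windowNm[2L])
  Fv <- approx(wd, intensities(donorEmission), xout = w,
               method = "linear", ties = "ordered")$y
  ev <- approx(wa, intensities(acceptorExtinction), xout = w,
               method = "linear", ties = "ordered")$y
  denom <- pracma::trapz(w, Fv)
  if (denom <= 0) stop("donor emission integrates to zero over the window")
  pracma::trapz(w, Fv * ev * w^4) / denom
}

#' Forster radius
#'
#' `R0 = 0.211 * (kappa^2 * phiD * etaInv4 * J)^(1/6)` with J in
#' M^-1 cm^-1 nm^4 gives R0 in Angstrom; the return value is converted to
#' nm. `etaInv4` is the refractive-index factor eta^-4 (0.3139 for
#' eta = 1.336, aqueous buffer); it is exposed as a parameter rather than
#' recomputed from eta so any literature value can be reproduced exactly.
#'
#' @param J spectral overlap integral, M^-1 cm^-1 nm^4 (> 0).
#' @param kappa2 dipole orientation factor (0.476 for parallel transition
#'   dipoles; 2/3 is the isotropic-average alternative).
#' @param phiD donor fluorescence quantum yield (> 0).
#' @param etaInv4 eta^-4 refractive-index factor (> 0).
#' @return Forster radius, nm.
#' @examples
#' forsterRadius(1.33e14)  # 2.53 nm
#' @export
forsterRadius <- function(J, kappa2 = 0.476, phiD = 0.15,
                          etaInv4 = 0.3139) {
  if (any(c(J, kappa2, phiD, etaInv4) <= 0))
    stop("all Forster-radius inputs must be positive")
  0.211 * (kappa2 * phiD * etaInv4 * J)^(1 / 6) / 10
}

#' FRET efficiency from donor intensities
#'
#' `E = 1 - F/F0`. A negative value (F above F0) is not an energy-transfer
#' result and is an error.
#'
#' @param F donor intensity with the acceptor present.
#' @param F0 donor intensity without the acceptor (> 0).
#' @return efficiency E in `[0, 1]`.
#' @export
fretEfficiency <- function(F, F0) {
  if (F0 <= 0) stop("F0 must be positive")
  if (F < 0) stop("F must be non-negative")
  if (F > F0) stop("F exceeds F0: negative efficiency is not a FRET result")
  1 - F / F0
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inversion of `E = R0^6 / (R0^6 + r^6)`:
#' `r = R0 * (1/E - 1)^(1/6)`.
#'
#' @param E transfer efficiency, strictly inside (0, 1).
#' @param R0Nm Forster radius, nm (> 0).
#' @return donor-acceptor distance, nm.
#' @examples
#' donorAcceptorDistance(0.077, 2.53)  # 3.83 nm
#' @export
donorAcceptorDistance <- function(E, R0Nm) {
  if (E <= 0 || E >= 1) stop("E must lie strictly inside (0, 1)")
  if (R0Nm <= 0) stop("R0 must be positive")
  R0Nm * (1 / E - 1)^(1 / 6)
}

#' FRET validity checks
#'
#' Energy transfer is a credible quenching route when the donor-acceptor
#' distance sits between 0.5 and 1.5 Forster radii and below 10 nm.
#'
#' @param rNm donor-acceptor distance, nm (> 0).
#' @param R0Nm Forster radius, nm (> 0).
#' @return `list(validRange=, within10nm=)`.
#' @export
fretValidity <- function(rNm, R0Nm) {
  if (rNm <= 0 || R0Nm <= 0) stop("distances must be positive")
  list(validRange = rNm > 0.5 * R0Nm && rNm < 1.5 * R0Nm,
       within10nm = rNm < 10)
}

#' Full FRET analysis from spectra
#'
#' Chains the energy-transfer computations: molar extinction of the
#' acceptor from its absorbance ([molarExtinction()]), spectral overlap
#' integral ([overlapIntegral()]), Forster radius ([forsterRadius()]),
#' single-point efficiency at the donor's emission maximum
#' ([fretEfficiency()]), donor-acceptor distance
#' ([donorAcceptorDistance()]) and validity checks ([fretValidity()]).
#'
#' @param donorEmission donor emission [Spectrum-class] (acceptor absent).
#' @param acceptorAbsorbance acceptor absorbance [Spectrum-class].
#' @param acceptorConcM acceptor concentration, M.
#' @param F,F0 donor intensities with/without acceptor at `emissionNm`;
#'   alternatively pass `E` directly.
#' @param E transfer efficiency; overrides `F`/`F0` when given.
#' @param emissionNm wavelength of the single-point efficiency read.
#' @param kappa2,phiD,etaInv4 constants of [forsterRadius()].
#' @param windowNm integration window of [overlapIntegral()].
#' @param pathlengthCm cuvette path length, cm.
#' @return A [FretResult-class].
#' @export
fretAnalysis <- function(donorEmission, acceptorAbsorbance, acceptorConcM,
                         F = NULL, F0 = NULL, E = NULL,
                         emissionNm = 340,
                         kappa2 = 0.476, phiD = 0.15, etaInv4 = 0.3139,
                         windowNm = c(285, 450), pathlengthCm = 1) {
  if (is.null(E)) {
    if (is.null(F) || is.null(F0))
      stop("supply either E or both F and F0")
    E <- fretEfficiency(F, F0)
  }
  eps <- molarExtinction(acceptorAbsorbance, acceptorConcM, pathlengthCm)
  J <- overlapIntegral(donorEmission, eps, windowNm)
  R0 <- forsterRadius(J, kappa2 = kappa2, phiD = phiD, etaInv4 = etaInv4)
  r <- donorAcceptorDistance(E, R0)
  v <- fretValidity(r, R0)
  new("FretResult",
      efficiencyE = E, JMcmNm4 = J, R0Nm = R0, rNm = r,
      kappa2 = kappa2, phiD = phiD, etaInv4 = etaInv4,
      windowNm = as.numeric(windowNm),
      validRange = v$validRange, within10nm = v$within10nm)
}

setMethod("show", "FretResult", function(object) {
  cat(sprintf(
    "FRET analysis\n  E = %.3g | J = %.4g M^-1 cm^-1 nm^4 | R0 = %.3g nm | r = %.3g nm\n  0.5 R0 < r < 1.5 R0: %s | r < 10 nm: %s\n",
    object@efficiencyE, object@JMcmNm4, object@R0Nm, object@rNm,
    if (object@validRange) "yes" else "no",
    if (object@within10nm) "yes" else "no"))
})
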