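#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T * dS / 1000`, with dH and dG in kJ mol^-1 and dS in
#' J mol^-1 K^-1 (the conventional mixed units of binding thermodynamics
#' tables).
#'
#' @param dHkJmol enthalpy, kJ mol^-1.
#' @param dSJmolK entropy, J mol^-1 K^-1.
#' @param temperatureK temperature, K (> 0).
#' @return Gibbs free energy, kJ mol^-1.
#' @examples
#' gibbs(18.93, 130.14, 310)  # -21.41 kJ/mol
#' @export
gibbs <- function(dHkJmol, dSJmolK, temperatureK) {
  if (any(temperatureK <= 0)) stop("temperature must be positive kelvin")
  dHkJmol - temperatureK * dSJmolK / 1000
}

#' Gibbs free energy directly from a binding constant
#'
#' `dG = -R * T * ln(Ka) / 1000` in kJ mol^-1. Reported as a diagnostic
#' alongside the enthalpy/entropy route of [gibbs()]: the two agree
#' exactly only when K_a lies exactly on the van't Hoff line.
#'
#' @param KaM binding constant, M^-1 (> 0).
#' @param temperatureK temperature, K (> 0).
#' @param R gas constant, J mol^-1 K^-1.
#' @return Gibbs free energy, kJ mol^-1.
#' @export
gibbsFromKa <- function(KaM, temperatureK, R = GAS_CONSTANT) {
  if (any(KaM <= 0)) stop("Ka must be positive")
  if (any(temperatureK <= 0)) stop("temperature must be positive kelvin")
  -R * temperatureK * log(KaM) / 1000
}

#' Intermolecular-force classification from the (dH, dS) sign pattern
#'
#' The classical sign rules for protein-ligand binding: positive dH and dS
#' indicate hydrophobic interactions; negative dH with positive dS,
#' electrostatic/ionic interactions; both negative, hydrogen bonding and
#' van der Waals forces; positive dH with negative dS, a non-spontaneous
#' association. A zero member adopts the sign of the non-zero member;
#' both zero falls back to `"hbond_vdw"` with a warning.
#'
#' @param dHkJmol enthalpy, kJ mol^-1.
#' @param dSJmolK entropy, J mol^-1 K^-1.
#' @return one of `"hydrophobic"`, `"electrostatic_ionic"`, `"hbond_vdw"`,
#'   `"nonspontaneous"`.
#' @examples
#' classifyForces(18.93, 130.14)   # hydrophobic
#' classifyForces(-13.26, 35.84)   # electrostatic_ionic
#' @export
classifyForces <- function(dHkJmol, dSJmolK) {
  if (dHkJmol == 0 && dSJmolK == 0) {
    warning("dH and dS are both zero; defaulting to hbond_vdw")
    return("hbond_vdw")
  }
  sH <- if (dHkJmol != 0) sign(dHkJmol) else sign(dSJmolK)
  sS <- if (dSJmolK != 0) sign(dSJmolK) else sign(dHkJmol)
  if (sH > 0 && sS > 0) "hydrophobic"
  else if (sH < 0 && sS > 0) "electrostatic_ionic"
  else if (sH < 0 && sS < 0) "hbond_vdw"
  else "nonspontaneous"
}

#' Van't Hoff thermodynamic analysis
#'
#' Ordinary least squares of `ln Ka` on `1/T`: the slope gives the binding
#' enthalpy (`dH = -R * slope`) and the intercept the entropy
#' (`dS = R * intercept`). Gibbs energies per temperature come primarily
#' from `dH - T*dS` ([gibbs()]); the `-RT ln Ka` values are carried as a
#' diagnostic (`dGfromKaByT`) — their residual against the primary route
#' measures how far the K_a fall off the fitted line. The force
#' classification of [classifyForces()] is applied to the regressed pair.
#'
#' @param kaByTemp named numeric vector, temperatures (K, names) to K_a
#'   (M^-1); or a list of [BindingFit-class] objects.
#' @param R gas constant, J mol^-1 K^-1.
#' @return A [ThermoResult-class]. With exactly two temperatures the line
#'   is exact by construction; the result is flagged `minimalDesign`.
#' @examples
#' vantHoff(c("290" = 2354, "300" = 3425, "310" = 3897))
#' @export
vantHoff <- function(kaByTemp, R = GAS_CONSTANT) {
  if (is.list(kaByTemp) &&
      all(vapply(kaByTemp, is, logical(1), "BindingFit"))) {
    temps <- vapply(kaByTemp, function(f) f@temperatureK, numeric(1))
    kas <- vapply(kaByTemp, function(f) f@KaM, numeric(1))
  } else {
    temps <- suppressWarnings(as.numeric(names(kaByTemp)))
    kas <- as.numeric(kaByTemp)
  }
  if (length(temps) < 2L)
    stop("van't Hoff analysis needs >= 2 distinct temperatures")
  if (anyNA(temps)) stop("temperatures must be supplied as names (K)")
  if (anyDuplicated(temps)) stop("duplicate temperatures")
  if (any(temps <= 0)) stop("temperature must be positive kelvin")
  if (any(kas <= 0)) stop("Ka must be positive")
  ord <- order(temps)
  temps <- temps[ord]
  kas <- kas[ord]
  x <- 1 / temps
  y <- log(kas)
  fit <- lm(y ~ x)
  dH <- -R * unname(coef(fit)[2L]) / 1000   # kJ/mol
  dS <- R * unname(coef(fit)[1L])           # J/mol/K
  r2 <- if (length(temps) == 2L) 1
        else suppressWarnings(summary(fit))$r.squared
  dG <- gibbs(dH, dS, temps)
  names(dG) <- format(temps)
  dGdiag <- gibbsFromKa(kas, temps, R)
  names(dGdiag) <- format(temps)
  spont <- dG < 0
  names(spont) <- format(temps)
  new("ThermoResult",
      dHkJmol = dH, dSJmolK = dS,
      dGkJmolByT = dG, dGfromKaByT = dGdiag,
      rSquared = r2,
      forceLabel = classifyForces(dH, dS),
      spontaneousByT = spont,
      minimalDesign = length(temps) == 2L)
}

#' @describeIn ThermoResult binding enthalpy, kJ mol^-1.
#' @param x a `ThermoResult`.
#' @export
setMethod("deltaH", "ThermoResult", function(x) x@dHkJmol)

#' @describeIn ThermoResult binding entropy, J mol^-1 K^-1.
#' @export
setMethod("deltaS", "ThermoResult", function(x) x@dSJmolK)

#' @describeIn ThermoResult Gibbs energy per temperature, kJ mol^-1.
#' @export
setMethod("deltaG", "ThermoResult", function(x) x@dGkJmolByT)

#' @describeIn ThermoResult force-classification label.
#' @export
setMethod("forceLabel", "ThermoResult", function(x) x@forceLabel)

#' @describeIn ThermoResult r-squared of the van't Hoff line.
#' @export
setMethod("rSquared", "ThermoResult", function(x) x@rSquared)

setMethod("show", "ThermoResult", function(object) {
  cat(sprintf(
    "Van't Hoff analysis%s\n  dH = %.4g kJ/mol | dS = %.4g J/mol/K | r^2 = %.4f\n  forces: %s\n",
    if (object@minimalDesign) " [minimal 2-temperature design]" else "",
    object@dHkJmol, object@dSJmolK, object@rSquared, object@forceLabel))
  for (Tn in names(object@dGkJmolByT))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol (%s; -RT lnKa: %.4g)\n",
                Tn, object@dGkJmolByT[[Tn]],
                if (object@spontaneousByT[[Tn]]) "spontaneous"
                else "non-spontaneous",
                object@dGfromKaByT[[Tn]]))
})
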