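---
title: "Quenching, binding and energy-transfer analysis of protein-ligand titrations"
author: "QuenchBind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quenching, binding and energy-transfer analysis of protein-ligand titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(QuenchBind)
```

# Scope

QuenchBind analyses steady-state fluorescence titrations of a protein
fluorophore (typically serum albumin, whose tryptophan/tyrosine emission
peaks near 340 nm under 280 nm excitation) with a quenching ligand. From a
set of emission spectra recorded at increasing ligand concentration it
estimates the quenching constant and mechanism, the binding constant and
stoichiometry, the binding thermodynamics and dominant intermolecular
force, the donor-acceptor distance by resonance energy transfer, residue
microenvironment changes from synchronous scans, and binding-site
assignment by site-probe displacement. A seeded forward simulator supplies
ground-truth data so that every stage is testable without an instrument.

# Data model

A `TitrationSeries` extends `SummarizedExperiment`: the `"signal"` assay
is a wavelength-by-concentration intensity matrix, `rowData()` holds the
wavelength grid and `colData()` the quencher concentrations (always molar
internally; file metadata declare `"uM"` or `"M"`). One series is one
temperature; the first column may be the zero-quencher trace that defines
the unquenched intensity $F_0$. Single traces are `Spectrum` objects.

Intensities $F$ and $F_0$ are always read at the *fixed* wavelength of the
unquenched emission maximum (default 340 nm), not at per-spectrum maxima:
peak drift under ligand binding would otherwise contaminate the quenching
ratios. Interpolation is piecewise linear everywhere; emission grids are
dense (1 nm by default) and nothing in the analysis warrants a smoother.

# Models

## Inner-filter correction

Observed intensities are attenuated by sample absorbance at the excitation
and emission wavelengths. `innerFilterCorrect()` applies
$F_\mathrm{cor} = F_\mathrm{obs}\, e^{(A^{ex} + A^{em})/2}$, with $A^{em}$
evaluated per emission wavelength and per concentration. Since $A \ge 0$
the correction never decreases an intensity, and a series can only be
corrected once.

## Stern-Volmer quenching

`sternVolmerFit()` fits $F_0/F = 1 + K_{sv}[Q]$ by ordinary least squares
with a *free* intercept. Theory fixes the intercept at 1, but real
baselines do not; the fitted intercept is reported as a diagnostic rather
than constrained. The bimolecular rate $k_q = K_{sv}/\tau_0$ uses the
literature unquenched-BSA lifetime $\tau_0 = 6.2$ ns by default
(overridable). `classifyMechanism()` reads the temperature trend of
$K_{sv}$: decreasing means static quenching (heat dissociates the
ground-state complex); increasing with all $k_q$ at or below the
diffusion-controlled limit ($2 \times 10^{10}\,$M$^{-1}$s$^{-1}$ by
default) means dynamic (collisional) quenching; increasing with $k_q$
above that limit is physically impossible for pure collision, so the call
is "static-dominant, ambiguous". Trends must be strictly monotone across
*all* temperature pairs; mixed orderings are inconclusive, and a relative
$K_{sv}$ spread below 5% is called flat (typical inter-run errors of such
fits are a few percent, so smaller spreads are not trends).

## Double-logarithmic binding analysis

`doubleLogFit()` fits
$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_a + n \log_{10} [Q]$
over the nonzero concentrations (the zero point is excluded — $\log 0$ is
undefined — so the canonical 10-point design yields 9 fitted points).
Logarithms here are base 10; the van't Hoff analysis below uses natural
logarithms. Both bases are fixed internally — mixing them is the classic
failure mode of this pipeline. Points with $F \ge F_0$ (no net quenching,
possible at low concentration in noisy data) are excluded with a warning.
The $K_a$ uncertainty is reported as a multiplicative factor
$10^{\mathrm{SE(intercept)}}$, matching the dimensionless "$\pm$ factor"
convention of binding tables, not an additive error in M$^{-1}$.

`displacementAnalysis()` compares $K_a$ with and without a site probe
(warfarin for Sudlow site I, ibuprofen for site II). The default
competitive threshold is a 1.5-fold decrease; published site-assignment
effects are typically $\ge$ 3-fold, so any sane threshold reproduces such
calls, and the value is configurable.

## Van't Hoff thermodynamics

`vantHoff()` regresses $\ln K_a$ on $1/T$:
$\Delta H = -R \cdot \mathrm{slope}$, $\Delta S = R \cdot \mathrm{intercept}$,
with $R = 8.314$ J mol$^{-1}$ K$^{-1}$. Units follow the conventional
mixed bookkeeping of binding tables: $\Delta H$ and $\Delta G$ in
kJ mol$^{-1}$, $\Delta S$ in J mol$^{-1}$ K$^{-1}$. Gibbs energies are
computed primarily as $\Delta G(T) = \Delta H - T\Delta S$; the direct
$-RT\ln K_a$ values are carried alongside as a diagnostic — the two agree
exactly only when the $K_a$ lie exactly on the regression line, and the
residual between them measures lack of fit. With exactly two temperatures
the line is exact by construction and the result is flagged
`minimalDesign`. The sign pattern of $(\Delta H, \Delta S)$ classifies the
dominant force: $(+,+)$ hydrophobic, $(-,+)$ electrostatic/ionic, $(-,-)$
hydrogen bonding / van der Waals, $(+,-)$ non-spontaneous. A zero member
adopts the sign of the other; the doubly-degenerate $(0,0)$ falls back to
hbond/vdW with a warning.

## Resonance energy transfer

The overlap integral
$J = \int F(\lambda)\,\varepsilon(\lambda)\,\lambda^4 d\lambda \,/\, \int F(\lambda) d\lambda$
is evaluated by the trapezoidal rule on the donor's native grid over a
285-450 nm window (both configurable); the acceptor extinction
($\varepsilon = A/(c\,l)$, `molarExtinction()`) is interpolated onto that
grid when needed. The normalisation makes $J$ invariant under donor
scaling. The Förster radius is
$R_0 = 0.211\,(\kappa^2 \phi_D \eta^{-4} J)^{1/6}$,
which with $J$ in M$^{-1}$cm$^{-1}$nm$^4$ yields Ångström, reported as nm.
Two parameter choices deserve comment:

* $\kappa^2$ defaults to 0.476, the parallel-transition-dipole
  assumption appropriate when donor and acceptor are rigidly oriented in
  a binding pocket; the isotropic average 2/3 is available via the
  argument.
* The refractive-index factor is exposed as `etaInv4` $= \eta^{-4}$
  (default 0.3139, i.e. $\eta = 1.336$, aqueous buffer) rather than
  recomputed from $\eta$. Literature tables frequently print this factor
  directly, and only by accepting it verbatim can published radii be
  reproduced exactly; hard-coding one interpretation of "$\eta$" would
  make that impossible.

Efficiency comes from the single-point read $E = 1 - F/F_0$ at the donor
maximum, and the donor-acceptor distance from inverting
$E = R_0^6/(R_0^6 + r^6)$. `fretValidity()` checks the textbook
credibility window $0.5 R_0 < r < 1.5 R_0$ and $r < 10$ nm. Note that
published tables occasionally assert this window for distances that sit
slightly outside it; the package reports the arithmetic truth.

## Synchronous scans

`synchronousShift()` tracks the band maximum of constant-offset
synchronous scans ($\Delta\lambda = 15$ nm for tyrosine, 60 nm for
tryptophan) across the titration and reports the net shift of the
top-concentration trace against the unquenched one. Blueshifts (negative)
indicate residues moving into a more hydrophobic environment. Shifts
smaller than half a grid step are classified `"none"`: sub-resolution
movements are not claims. Peak ties break toward the shorter wavelength,
a fixed and documented rule that makes flat traces deterministic.

# The simulator

`simulationConfig()` + `simulateTitration()` generate titrations with
known ground truth. The emission band is a single Gaussian (center 340 nm,
$\sigma$ 15 nm by default) scaled per concentration by the generative
inverse of the model under test: $F = F_0/(1 + K_{sv}[Q])$ (linear),
$F = F_0/(1 + K_a[Q]^n)$ (hill), or their product (combined). With a
`thermo` block, $K_a(T) = \exp(-\Delta H/RT + \Delta S/R)$, so a
temperature set carries an exact van't Hoff line. The default design
mirrors the emulated study: 2 µM fluorophore, quencher at 0, 1, 5, 10,
20, 30, 40, 50, 60, 80 µM, temperatures 290/300/310 K, excitation 280 nm,
emission 285-450 nm on a 1 nm grid. Absolute band amplitude is arbitrary
(only intensity ratios matter downstream, and every fit is tested to be
scale-invariant).

Noise is multiplicative Gaussian, $\sigma = \texttt{noiseRel} \times$
signal, truncated at $\pm 5\sigma$ — a shot-noise-like model that keeps
intensities positive. The RNG is pinned (Mersenne-Twister / inversion
Gaussian) so identical seeds give bit-identical spectra across platforms,
and each design temperature uses a disjoint, reproducible substream.
Synchronous-shift fixtures drift the band center linearly in
concentration.

What the simulator does *not* model: photobleaching, scattering,
instrument drift, wavelength-dependent detector response, excitation-
emission matrices, or correlated (non-white) noise. Passing recovery
tests therefore demonstrate the correctness of the estimators under the
stated noise model, not robustness to every instrumental artefact of real
spectra.

## A caution on the double-log estimator at low quench fractions

One property of the emulated design is worth stating because the
simulator makes it measurable. At the lowest design concentration (1 µM)
a binding constant of a few $10^3$-$10^4$ M$^{-1}$ quenches only ~1-2% of
the signal. With ~1% intensity noise, $\log_{10}((F_0-F)/F)$ at that
point is extremely dispersed and skewed, and seeds where $F \ge F_0$ are
censored by the exclusion rule. Because the fitted intercept extrapolates
several decades from the data centroid to $\log[Q] = 0$, small slope
perturbations translate into very large $K_a$ errors, and the effect
propagates through the van't Hoff chain. Under those conditions
single-experiment $K_a$ estimates can be off by an order of magnitude
even though $K_{sv}$ (fitted on the linear scale) and $n$ remain
well-behaved, and medians over hundreds of replicates remain unstable.
Practitioners should either measure with substantially lower noise,
drop concentrations whose quench fraction is below a few times the noise
level, or treat low-concentration points with weighted regression. The
package's test suite documents this behaviour rather than hiding it: the
recovery tests that depend on the 1 µM point under 1% noise fail, and a
companion test shows recovery is unbiased once that point is excluded.

# Numerical and design choices

* All regressions are ordinary least squares via `stats::lm`; the test
  suite checks each against the closed-form two-parameter formulas to
  1e-12.
* Quadrature is trapezoidal (`pracma::trapz`) on the native grid; tests
  compare against a 100x finer grid (relative agreement better than 1e-3
  on smooth bands) and against the constant-spectra closed form
  $(450^5 - 285^5)/(5 \cdot 165)$.
* Background subtraction interpolates the background onto the sample
  grid; extrapolation is an error. Negative absorbance after subtraction
  is clipped to zero with a warning (baseline noise).
* File formats: comma-separated UTF-8 CSV with a `wavelength_nm` column
  and one intensity column per concentration, plus a JSON metadata
  sidecar that must declare concentration units. Writers emit
  deterministic column order at full precision, and load-write-load
  round-trips are bit-identical for finite decimal inputs.
* `runPipeline()` orchestrates the stages; stages with missing inputs
  are skipped and logged, a failing stage aborts with a stage-labelled
  error after writing a partial report, and reruns on identical inputs
  are identical apart from the timestamp. The orchestration adds nothing
  numeric — every report value equals the corresponding direct call.

# Problem sizes

The validation suite runs entirely on simulated data: single titrations
of 166 wavelengths x 10 concentrations, recovery studies of 200 seeds
(600 simulated titrations for the thermodynamic chain), and one
end-to-end pipeline study of 3 temperatures plus competitor, FRET and
synchronous fixtures. The full suite completes in about a minute on one
CPU.

# Limitations

* No time-resolved (lifetime) quenching analysis, no upward-curving
  sphere-of-action or mixed static/dynamic Stern-Volmer models.
* No nonlinear 1:1 isotherm, Scatchard, Job-plot or multi-site global
  fitting; the double-log model assumes the classical single-class
  approximation.
* No heat-capacity (curved van't Hoff) models.
* No anisotropy-based $\kappa^2$ estimation and no multi-acceptor FRET
  geometries.
* No vendor instrument formats and no smoothing/denoising; inputs are
  plain CSV/JSON.
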