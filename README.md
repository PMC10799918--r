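# QuenchBind

Quantitative analysis of protein–ligand binding from steady-state
fluorescence titrations, for biophysicists and toxicologists who
characterise how small molecules (drugs, pesticides, dyes) bind serum
albumin and similar fluorescent proteins. Given emission spectra of a
fixed protein concentration titrated with increasing ligand, QuenchBind
estimates how strongly, where, and by what forces the ligand binds —
without any instrument-vendor software.

## What it computes

* **Stern–Volmer quenching** — OLS fit of
  `F0/F = 1 + Ksv·[Q]`, the bimolecular rate `kq = Ksv/τ0`
  (τ0 = 6.2 ns for unquenched BSA), and a static/dynamic mechanism call
  from the temperature trend of `Ksv` and the diffusion limit
  (2×10¹⁰ M⁻¹s⁻¹).
* **Binding constant and stoichiometry** — OLS fit of
  `log₁₀((F0−F)/F) = log₁₀Ka + n·log₁₀[Q]`.
* **Thermodynamics** — van't Hoff regression `lnKa = −ΔH/RT + ΔS/R`,
  Gibbs energy `ΔG = ΔH − TΔS`, and force classification from the signs
  of (ΔH, ΔS): (+,+) hydrophobic, (−,+) electrostatic/ionic, (−,−)
  H-bond/van der Waals.
* **FRET geometry** — overlap integral
  `J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ`, Förster radius
  `R0 = 0.211(κ²·φD·η⁻⁴·J)^{1/6}`, efficiency `E = 1 − F/F0`, and
  donor–acceptor distance `r = R0(1/E − 1)^{1/6}`.
* **Site assignment** — fold change of `Ka` under site-probe
  co-incubation (warfarin = site I, ibuprofen = site II).
* **Microenvironment** — peak shifts of Δ15/Δ60 synchronous scans.
* **Inner-filter correction** — `Fcor = Fobs·exp((Aex+Aem)/2)`.
* **A seeded simulator** of the whole experiment with known ground
  truth, used throughout the test suite.

Data live in Bioconductor containers: a `TitrationSeries` extends
`SummarizedExperiment` (wavelength × concentration signal matrix with
experiment metadata); spectra are read/written as plain CSV with a JSON
metadata sidecar.

## Worked example

Simulate a three-temperature titration study (2 µM fluorophore, ligand
0–80 µM, 290/300/310 K) whose binding constants follow an exact van't
Hoff law with ΔH = 18.93 kJ/mol and ΔS = 130.14 J/mol/K, then run the
analysis chain:

```r
library(QuenchBind)

cfg <- simulationConfig("hill_binding", nSites = 0.89,
                        thermo = list(dH_J_mol = 18930,
                                      dS_J_mol_K = 130.14),
                        seed = 1)
series <- simulateTemperatureSet(cfg)

sternVolmerFit(series[["310"]])
#> Stern-Volmer fit (T = 310 K, 10 points)
#>   K_sv = 1.146e+04 +/- 2e+02 M^-1 | k_q = 1.848e+12 M^-1 s^-1 (tau0 = 6.2e-09 s)
#>   intercept = 1.0221 | r^2 = 0.9977

doubleLogFit(series[["310"]])
#> Double-log binding fit (T = 310 K, 9 points)
#>   K_a = 4058 M^-1 (x/ 1) | n = 0.89 +/- 2.9e-16 | r^2 = 1.0000

vantHoff(lapply(series, doubleLogFit))
#> Van't Hoff analysis
#>   dH = 18.93 kJ/mol | dS = 130.1 J/mol/K | r^2 = 1.0000
#>   forces: hydrophobic
#>   dG(290 K) = -18.81 kJ/mol (spontaneous; -RT lnKa: -18.81)
#>   dG(300 K) = -20.11 kJ/mol (spontaneous; -RT lnKa: -20.11)
#>   dG(310 K) = -21.41 kJ/mol (spontaneous; -RT lnKa: -21.41)
```

Reading the output: the ligand binds with moderate affinity
(`K_a ≈ 4.1×10³ M⁻¹`) at a single non-cooperative site (`n ≈ 0.9`); the
quenching rate far exceeds the diffusion limit, so the loss of
fluorescence reflects ground-state complex formation; positive ΔH and ΔS
mean hydrophobic contacts dominate, and the negative ΔG at every
temperature means binding is spontaneous. (This noiseless simulation
recovers the configured truth; the k_q of ~1.8×10¹² M⁻¹s⁻¹ here is the
Stern–Volmer slope of hill-model data divided by τ0.)

`runPipeline(config)` chains every stage (correction → quenching →
mechanism → binding → thermodynamics → FRET → displacement → synchronous
shifts) from in-memory objects or CSV/JSON paths and writes a JSON
report plus summary tables. `inst/scripts/quenchbind.R` exposes the same
stages as shell subcommands (`run`, `simulate`, `quench`, `bind`,
`thermo`, `fret`).

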