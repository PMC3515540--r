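---
title: "Models and methods behind stabfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stabfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabfit)
```

stabfit implements the quantitative core of an equilibrium
protein-stability study for dimeric, multi-domain proteins of the
Hsp40/DnaJ type: chemical unfolding through a partially folded monomeric
intermediate, calorimetric deconvolution of two thermal transitions,
heat-capacity estimation from perturbed scans, hydrodynamic transition
midpoints, and tryptophan-fluorescence probes. This vignette states the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Three-state chemical unfolding

The linear extrapolation method (LEM) assumes each transition free
energy is linear in denaturant concentration $d$:
$\Delta G_i(d) = \Delta G_i^{\circ} - m_i d$, with the $m$-value
proportional to the surface area newly exposed in that step. For the
scheme $N \rightleftharpoons I \rightleftharpoons U$,

$$K_1 = e^{-(\Delta G_{NI}^{\circ} - m_{NI} d)/RT}, \quad
  K_2 = e^{-(\Delta G_{IU}^{\circ} - m_{IU} d)/RT},$$

the species fractions are $f_N = 1/Z$, $f_I = K_1/Z$,
$f_U = K_1 K_2 / Z$ with $Z = 1 + K_1 + K_1 K_2$, and the observable is
the population-weighted plateau signal
$Y = Y_N f_N + Y_I f_I + Y_U f_U$. Midpoints are the exact ratios
$C_m = \Delta G^{\circ}/m$; `fit_three_state()` computes them from the
fitted parameters, so $C_m \cdot m = \Delta G^{\circ}$ holds to machine
precision by construction.

Assumptions worth stating:

* **Concentration independence.** The native state of these proteins is
  a dimer, so a rigorous dimer-unfolding model would carry an explicit
  protein-concentration term in $K_1$. The model fitted here is the
  concentration-independent form applied to data collected at one
  loading concentration; fitted $\Delta G^{\circ}$ values are therefore
  apparent stabilities at that concentration, not dimer dissociation
  energies. This is a deliberate scope decision, and the main known
  limitation of the chemical-unfolding module.
* **Signal entry points.** Either raw ellipticity or a pre-normalized
  fraction-unfolded curve can be fitted; `raw_to_fraction()` converts
  between them with linear native/unfolded baselines and rejects
  baselines that coincide within tolerance (default $10^{-8}$ signal
  units) anywhere on the grid.
* **Intermediate plateau.** Whether $Y_I$ should be fitted or pinned is
  genuinely open for curves whose intermediate is never highly
  populated. Both modes are supported; $Y_I$ is free by default, and
  `fix_yi` pins it when independent information exists.

Numerical choices: fitting is Levenberg–Marquardt least squares
(`minpack.lm`). Self-initialization takes plateaus from the outer 10% of
points, midpoint guesses at the 25%/75% crossings of the smoothed
signal, $m$-values of 2 kcal/mol/M (a typical slope for a ~100-residue
cooperative unit) and $\Delta G^{\circ} = m C_m$. Bounds are
$m \in (0, 10]$ kcal/mol/M and $\Delta G^{\circ} \in (0, 50]$ kcal/mol.
The transition order is enforced by construction — the optimizer works
on $(\Delta G_{NI}, m_{NI}, m_{IU}, \log(C_{m,IU} - C_{m,NI}))$, so
$C_{m,NI} < C_{m,IU}$ for every candidate, which is the tie-break that
keeps the two transitions identifiable. Standard errors come from the
Gauss–Newton curvature $\sigma^2 (J^\top J)^{-1}$ evaluated in the
natural parameterization, with delta-method errors for the $C_m$
ratios; a singular curvature yields `NA` errors rather than a failure.
A fit requires at least 8 points and more points than free parameters.
The gas constant is $R = 1.987\times10^{-3}$ kcal/mol/K and the default
temperature 293.15 K (20 °C) throughout.

## DSC analysis

**Baseline.** `subtract_baseline()` fits straight lines through
user-chosen pre- and post-transition windows (each must hold ≥ 5 points
and not overlap) and subtracts a connection of the two. The default
connection weights the lines by the cumulative normalized excess-heat
area — the standard sigmoidal chemical baseline — refined by a short
fixed-point iteration that starts from a linear ramp; a plain chord is
available via `method = "chord"`. A scan that is exactly one straight
line yields identically zero excess heat under either rule.

**Enthalpy.** `integrate_dHcal()` is a trapezoidal integral of excess
heat capacity over a window, with the window edges interpolated exactly.

**Deconvolution.** The "non-two-state" model is a sum of independent
two-state transitions, each with its own calorimetric (area) and van't
Hoff (shape) enthalpy:

$$C_p^{ex}(T) = \sum_i \frac{\Delta H_{cal,i}\, \Delta H_{vH,i}}{R T^2}
  \frac{K_i}{(1+K_i)^2}, \qquad
  K_i = e^{-(\Delta H_{vH,i}/R)(1/T - 1/T_{m,i})}.$$

The integral of each term is $\Delta H_{cal,i}$ and the peak height at
$T_m$ is $\Delta H_{cal}\Delta H_{vH}/(4RT_m^2)$, which is how the two
enthalpies separate area from shape. $\Delta H_{vH}$ is free by default;
`constrain_vh = TRUE` ties it to $\Delta H_{cal}$ for strict two-state
shapes (which of the two conventions the original instrument software
used is not documented, so both are provided). Initialization peels
transitions sequentially: fit one, seed the next from the largest
positive residual peak, refit jointly — this resolves shoulder
transitions that are not local maxima, the common situation when a small
second transition overlaps a dominant first one. Transitions are
returned Tm-ascending; a fitted separation under 1 °C only warns,
because the fit is then honest but poorly identified. Temperatures are
converted to Kelvin internally and reported in °C.

**Reversibility.** `reversibility_fraction()` is the rescan/first-scan
ratio of excess-heat areas over the shared temperature window, with the
conventional 95% acceptance threshold. It is a QC gate only: analysis
uses first scans.

## Kirchhoff heat-capacity regression

Across scans perturbed by sub-denaturing urea (0.25–2 M), the midpoint
shifts and the calorimetric enthalpy follows the Kirchhoff relation with
a temperature-independent $\Delta C_p$:
$\Delta H_{cal}(T_m) = \Delta H_{ref} + \Delta C_p (T_m - T_{ref})$.
`fit_kirchhoff()` is an ordinary least-squares line (unweighted by
default — per-point errors are rarely available for first-scan
integrals, and weighting is exposed through the `weights` argument);
$T_{ref}$ defaults to the highest $T_m$, i.e. the unperturbed scan. Urea
concentration is carried as metadata only and never regressed on. At
least 3 pairs with distinct $T_m$ are required; identical midpoints are
a rank-deficiency error. `per_residue_dcp()` normalizes
$1000\,\Delta C_p / n_{res}$ to cal/mol/K per residue and reports one
decimal by default (the conventional precision for this quantity);
`digits = NULL` gives the exact ratio, which inverts exactly.

## Logistic transition midpoints

Thermal CD melting curves and the hydrodynamic series (s₂₀,w or molar
mass versus urea) share one four-parameter logistic,

$$y(x) = \mathrm{lower} + \frac{\mathrm{upper} - \mathrm{lower}}
  {1 + e^{(\mathrm{mid} - x)/\mathrm{width}}},$$

so that $T_{m,CD}$, $C_{m,AUC}$ and $C_{m,SEC\text{-}MALLS}$ are
directly comparable numbers. Decreasing transitions simply have
upper < lower. The fit multi-starts from three width guesses (a
25–75% crossing-based estimate and two fractions of the x-range) and
keeps the lowest residual sum; the width is bounded below by a quarter
of the median grid spacing, because a transition narrower than the
sampling is indistinguishable from a step and that degenerate optimum
has singular curvature. The midpoint is constrained to the sampled
range. Flat data raise a "no transition detectable" error; strongly
non-monotone data warn but still fit. Curves that do not reach a
plateau fit with honestly inflated midpoint errors.

## Hydrodynamics

`correct_s_to_s20w()` applies the standard solvent correction
$s_{20,w} = s_{obs} (\eta_b/\eta_{w,20})
(1 - \bar v \rho_{w,20})/(1 - \bar v \rho_b)$ with water-at-20 °C
constants 1.002 cP and 0.99823 g/mL, rejecting non-positive buoyancy
terms. `extrapolate_s0()` is the OLS intercept of $s_{20,w}$ versus
loading concentration (linear concentration dependence only, matching
how such data are analyzed); one concentration returns that value
flagged with infinite error. `urea_buffer_props()` replaces the desktop
solvent-property program used in this field with published empirical
relations: water density from the Kell equation, water viscosity from
the Vogel equation, the urea density increment from the weight-fraction
expansion $\rho = \rho_w + 0.2658\,W + 0.0330\,W^2$ solved by fixed
point, and a quadratic relative-viscosity polynomial in molarity
calibrated against tabulated urea-solution data; it is defined on
0–9 M. Of these, only the 0 M limits and monotonic growth are contract
guarantees — absolute accuracy at high molarity is that of the
published relations. `vbar_from_sequence()` is the mass-weighted
Cohn–Edsall residue table shipped in code. `classify_oligomer()` calls
a mass ratio within 15% of 1 a monomer and within 2×15% of 2 a dimer —
that tolerance is a pipeline choice reflecting typical SEC-MALLS
accuracy, not a published criterion.

## Fluorescence

The center of spectral mass $\langle\lambda\rangle = \sum \lambda_i
F_i / \sum F_i$ is scale-invariant and bounded by the wavelength range.
Stern–Volmer fitting regresses $F_0/F$ on quencher concentration; the
intercept is free by default and reported as a linearity diagnostic
(collisional quenching predicts 1), with `force_intercept = TRUE`
matching the textbook equation exactly. Note a statistical subtlety the
package's tests account for: $F_0$ appears in every ratio, so its
measurement noise shifts the whole line coherently and the slope's true
sampling spread is several times the OLS standard error under
multiplicative intensity noise.

## Synthetic data

Each generator draws from the forward model of its matched fit plus
Gaussian noise (multiplicative for quenching intensities, additive
elsewhere), under a single seed with deterministic per-array
sub-streams, so outputs are bit-reproducible and adding an output never
shifts existing draws. Default grids copy the instrument protocols:
urea 0–6 M in 0.1 M steps, 15–90 °C in 0.25 °C steps, acrylamide
0–100 mM in 10 mM steps. Default truths are the published wild-type
values (ΔG 7.2/8.0 kcal/mol, m 2.1/1.7 kcal/mol/M, Tm 59.0/67.7 °C, ΔH
154.0/29.5 kcal/mol, ΔCp 4.0 kcal/mol/K, K_SV 11.1 M⁻¹); where no value
is published — logistic widths, for example — the defaults are chosen
once to match the described transition spans (a 0.3–0.4 M width
reproduces a 1–3 M urea transition; 2.5 °C reproduces melting over
55–75 °C) and noise scales are typical instrument noise (0.5–1% of
amplitude for CD and intensities, 0.02–0.05 kcal/mol/K for DSC).

What the generators deliberately do **not** emulate: photobleaching,
thermal lag and scan-rate kinetics, optical artifacts, aggregation
above 90 °C, and instrument-specific baselines beyond a straight line.
Passing recovery tests therefore demonstrates the correctness and
statistical calibration of the fitting stack, not robustness to every
real-instrument pathology.

## Pipeline

`run_pipeline()` validates every referenced input before computing
anything, runs the declared stages independently (a failed stage leaves
an explicit gap and a nonzero-status signal rather than aborting the
rest), writes per-stage key-value fit records, a manifest with input
hashes and the seed, and a summary rounded at the conventional one
decimal for energies, midpoints, temperatures, enthalpies and
heat-capacity terms. Runs on identical inputs are byte-identical.

## Problem sizes

The test-suite and acceptance experiments run at the protocol sizes the
models describe: 61-point unfolding curves, 301-point thermograms,
8-point Kirchhoff series, 11-point quenching and sedimentation series,
property checks over 20–100 random draws. At these sizes the whole
suite completes in a few seconds.
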