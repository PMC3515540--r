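Package: stabfit
Title: Thermodynamic and Hydrodynamic Analysis of Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium and thermal protein-stability analysis for
    chaperone-scale proteins: three-state chemical (urea) unfolding fits by
    the linear extrapolation method, differential scanning calorimetry
    thermogram baseline treatment and non-two-state deconvolution, Kirchhoff
    heat-capacity regression, sedimentation-coefficient standardization to
    s20,w with sequence-based partial specific volumes, sigmoid transition
    midpoints for hydrodynamic and circular-dichroism series, and
    Stern-Volmer fluorescence quenching. Includes seeded synthetic-data
    generators with known ground truth for every input class and a
    config-driven pipeline that aggregates per-protein stability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    seqinr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
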