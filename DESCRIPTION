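Package: notchdimer
Title: Ligand-Dimer Cis-Inhibition Models of Notch Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation models of juxtacrine
    Notch signalling in which ligand monomers drive trans-activation (and
    cis-activation) of the Notch receptor while ligand dimers/oligomers drive
    cis-inhibition. Provides the general ligand-dimerization model, its
    mutual-inactivation and dimer-only (T1) reductions with closed-form steady
    states, cis-activation scenarios, oligomer-size and subcellular-compartment
    extensions, single-cell and two-cell simulations, dose-response sweeps,
    multicellular lattice simulations of wing-vein and dorsoventral-boundary
    patterning with Fringe gating, local parameter-sensitivity analysis, and a
    command-line interface over figure-panel scenario presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
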