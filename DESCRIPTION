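Package: cidtherm
Title: Gas-Phase Dissociation Kinetics and Thermodynamics from Native MS
    Breakdown Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of collision-induced dissociation (CID) breakdown
    curves of non-covalent protein oligomer ions measured by native
    electrospray mass spectrometry. Computes monoisotopic masses, m/z
    values and atom counts for proteoform oligomer ions, enumerates
    dissociation reactions of two-proteoform trimer mixtures, extracts and
    normalizes per-voltage ion intensities into dissociation courses, fits
    Boltzmann sigmoids with midpoint tangent characteristics, converts
    collision-voltage dependencies to effective-temperature dependencies,
    and extrapolates apparent rate constants, quasi-equilibrium constants
    and Gibbs energy, enthalpy and entropy terms to ambient temperature
    via Arrhenius and Gibbs-Helmholtz regressions. Includes a synthetic
    experiment generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
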