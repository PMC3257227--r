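Package: ribodyn
Title: Residue-Resolved Stability and Dynamics Analysis of Monomeric Ribonucleases
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the residue-resolved characterisation of a
    small globular protein (the monomeric derivative of bovine seminal
    ribonuclease, mBS, 124 residues) by solution NMR and molecular dynamics:
    hydrogen/deuterium exchange kinetics with intrinsic-rate prediction,
    protection factors and opening free energies; Lipari-Szabo model-free
    analysis of 15N relaxation with a global rotational correlation time,
    reduced spectral-density mapping and CSA/DD cross-correlation based
    exchange detection; per-residue two-state urea denaturation fits;
    paramagnetic-probe (TEMPOL) surface-accessibility profiling; and
    trajectory post-processing (RMSF, hydrogen-bond percentage lifetimes,
    hydration-site density grids, probe-sphere atom depth indexes).  A
    synthetic-data module generates every input type with known ground truth
    so all pipelines are testable without experimental spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
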