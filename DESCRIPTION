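Package: quenchlab
Title: Fluorescence Quenching and Binding Thermodynamics for Drug-Serum-Albumin Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spectroscopic and electrochemical
    characterization of small-molecule binding to serum albumins.
    Implements inner-filter-effect correction of fluorescence titrations,
    Stern-Volmer quenching analysis with mechanism classification,
    double-logarithmic binding fits with free-ligand depletion correction,
    Van't Hoff thermodynamics with Ross-Subramanian force classification,
    circular dichroism mean-residue-ellipticity conversion and alpha-helix
    estimation, synchronous and excitation-emission-matrix fluorescence
    metrics with Rayleigh masking, differential pulse voltammetry peak
    metrics, and site-marker competition scoring. A synthetic-data module
    generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
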