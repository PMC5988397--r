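Package: qmstitch
Title: Stitched Relative Energy Profiles for Enzyme-Catalysed Hydrolysis
    and Transglycosylation from QM Cluster-Model Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising whole relative energy profiles of
    enzyme-catalysed hydrolysis versus transglycosylation from quantum-chemical
    cluster-model single-point energies. Reads species-energy tables and
    Gaussian-style text logs, converts absolute electronic energies (hartree)
    to per-step relative energies (kcal/mol), computes rigid-rotor
    harmonic-oscillator thermochemistry and the two-dielectric dissociation
    free-energy correction, stitches half-reactions of differing chemical
    composition into one profile relative to the reactant complex, and renders
    functional-comparison tables and stepped profile diagrams. Includes a
    synthetic-data generator with prescribed barriers for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
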