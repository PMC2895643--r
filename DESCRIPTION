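Package: eyeCPM
Title: Glazier-Graner-Hogeweg Simulation of Interommatidial Cell Patterning
    in the Drosophila Pupal Eye
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional Glazier-Graner-Hogeweg (Cellular Potts)
    simulator of the pupal-eye epithelium of Drosophila, in which
    interommatidial precursor cells (IPCs) resolve into the hexagonal
    lattice of secondary and tertiary pigment cells that surrounds each
    ommatidial core. Cells live on a periodic square lattice and evolve by
    Metropolis-accepted boundary copy attempts against an effective energy
    of type-dependent adhesion plus area and perimeter constraints. Two
    tissue-specific mechanisms drive patterning: contact-length-gated
    programmed cell death of IPCs and linear apical-surface expansion of
    ommatidial cores. The package provides a synthetic eye-field generator,
    a label-image importer/exporter, scoring of emergent secondary and
    tertiary cells, named perturbation presets (reduced death, flat and
    anti-preferential adhesion, blocked expansion, growing IPCs), and a
    batch experiment runner with parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    png,
    mgcv,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
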