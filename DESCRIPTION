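Package: oxychip
Title: Oxygen Transport Simulation and Phosphorescence Oximetry for
    Double-Layer Microfluidic Hypoxia Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models oxygen-tension control in double-layer PDMS microfluidic
    devices used for three-dimensional cell culture under spatiotemporal
    oxygen heterogeneity. Provides a finite-volume solver for steady and
    transient oxygen transport across multi-material domains with Henry's-law
    partition interfaces, Peclet-number flow-rate utilities and design sweeps
    over gas-channel and barrier-film placement; a ratiometric Stern-Volmer
    calibration pipeline converting phosphorescence image stacks of
    oxygen-sensitive nanoparticles to oxygen tension; migration and
    proliferation statistics for single-cell tracks (speed series,
    subpopulation splits, regional counts, Kruskal-Wallis with Dunn post-hoc
    comparisons); and seeded synthetic-data generators (forward camera model,
    oxygen-dependent persistent random walks) so every analysis stage can be
    exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
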