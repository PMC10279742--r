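Package: hexbundle
Title: Ensemble Analysis of Six-Helix DNA Bundle Nanopores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing conformational ensembles of the six-helix
    DNA bundle (6HB) nanopore motif: helix-axis fitting and kink angles at
    the mid-duplex nick, lumen width profiling between opposing duplexes,
    pore height and outer width, RMSD/RMSF, base-pair breakage statistics,
    and GROMOS-style conformational clustering. Includes bootstrap ensemble
    statistics over simulation replicas, number-density profiling of ions
    and water along the membrane normal, and post-processing of
    computational-electrophysiology ion-swap ledgers into per-slice
    currents, current-voltage datasets, conductance fits and conductance-
    state distributions. A fully seeded synthetic-data module generates
    6HB-like bead ensembles, ion fields and ohmic swap ledgers with known
    ground truth so every analysis stage is testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
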