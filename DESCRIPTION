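Package: alchnet
Title: Alchemical-Path-Aware Graph Neural Network for Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cumulative alchemical free energies at each lambda
    window of an alchemical transformation with a path-aware graph neural
    network over protein-ligand complex graphs, assembles relative and
    absolute binding free energies (RBFE/ABFE) from thermodynamic-cycle
    legs, and optimizes lambda-window schedules so that the free-energy
    difference between adjacent windows stays below a threshold. Includes
    reliability-weighted training on window-level labels and a synthetic
    alchemical-path data generator for desk-scale training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
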