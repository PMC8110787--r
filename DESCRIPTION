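Package: turgorcfm
Title: Micro-Indentation Analysis and Pressurized Shell Simulation for
    Single-Cell Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for indentation-based mechanical characterization of
    turgid plant cells and small organisms. Processes raw
    force-displacement records into compliance-corrected apparent
    stiffness values, aggregates them into per-specimen intine/exine
    stiffness ratios and the associated group statistics, and builds
    cylindrical "unfolded" stiffness maps of nematodes. A nonlinear
    finite-element simulator of a pressurized two-layer pollen-wall
    shell (solid wedge elements, follower turgor pressure, rigid
    spherical indenter) and its reduced spherical-shell models link the
    measured apparent stiffness to wall elasticity and turgor pressure.
    Seeded synthetic-data generators emulate the instrument and the
    study populations so every pipeline stage can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
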