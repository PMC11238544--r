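Package: mfir
Title: Mean Force Integration for Free-Energy Surfaces from Biased Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs free-energy surfaces in one- and two-dimensional
    collective-variable space from biased molecular simulations by mean force
    integration (MFI). Supports static biases (harmonic restraints, walls),
    metadynamics and well-tempered metadynamics hill logs in the PLUMED
    HILLS/COLVAR text dialects, and arbitrary combinations of simultaneous
    biases. Independent, asynchronous simulations are merged into a single
    surface by density-weighted averaging of window mean forces; local and
    global convergence are quantified on the fly through the weighted variance
    of window forces, the explored-volume fraction, and their ratio. Includes
    a Langevin simulator on analytical model potentials for self-contained
    campaigns, finite-difference and Fourier integration of the mean force,
    cross-simulation variance, and bootstrap error estimation over independent
    replicas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
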