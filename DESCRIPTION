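Package: discSPT
Title: Diffusive-State Analysis of Single-Particle Tracking in Retinal Disc Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-particle tracking data from
    photoreceptor disc membranes. Provides Markov-switching Brownian motion
    simulation in confined disc geometry with localization noise, time-averaged
    mean-square-displacement (MSD) analysis with short-lag diffusion-coefficient
    estimation and trajectory quality filters, a variational-Bayes hidden Markov
    model over displacement sequences with maximum-evidence selection of the
    number of diffusive states and bootstrap uncertainty, hydrodynamic sizing of
    membrane inclusions via an extended Saffman-Delbrueck relation, a
    stoichiometric model of transducin engagement by photoactivated rhodopsin,
    and fluorescence-movie analysis of transient receptor clusters (spot
    detection, linking, exponential lifetime fitting, kymographs and radial
    confinement profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
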