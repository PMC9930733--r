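Package: cidfrag
Title: Statistical Fragmentation and Energy Partitioning in Collision-Induced
    Dissociation of Hydrated Cluster Ions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling collision-induced dissociation (CID) of
    microhydrated amino-acid cluster cations such as Cys(H2O)n+ and
    Cys(H2O)nH+. Implements a fragment thermochemistry database with
    exhaustive fragmentation-channel enumeration (including clustered versus
    sequential water loss), harmonic vibrational state counting by the
    Beyer-Swinehart algorithm, classical rotational and translational
    densities of states, microcanonical breakdown curves by exact
    channel enumeration and by Metropolis Monte Carlo sampling, a forward
    model from centre-of-mass collision energy to observed fragment
    intensities with a two-component (ergodic Gaussian plus discrete
    non-ergodic) energy-deposition distribution, inverse fits for appearance
    energies and for the deposition distribution, post-analysis of
    dissociation trajectories by a distance-cutoff fragment criterion, and
    synthetic-data generators with known ground truth for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
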