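Package: pmfbind
Title: Umbrella Sampling, WHAM, and State-Dependent Binding Free Energies
    for Ion-Channel Block
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing one-dimensional potentials of mean
    force (PMF) from umbrella-sampling window data by the weighted
    histogram analysis method (WHAM), converting bulk-anchored PMFs into
    effective dissociation constants and standard binding free energies
    under a flat-bottom cylindrical restraint, and fitting the standard
    patch-clamp measurement models (Hill concentration-response,
    single-exponential use-dependent block, Boltzmann activation).
    Includes a synthetic-data module that generates biased Boltzmann
    trajectories from analytic ground-truth potentials and noisy
    electrophysiology curves, so the whole inference chain is testable
    end to end, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
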