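Package: gctraj
Title: Generalized-Correlation and Essential-Dynamics Analysis of
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to characterize cooperative domain motions in
    biomolecular dynamics trajectories. Implements the mutual-information
    generalized correlation coefficient of Cα fluctuations via a
    Kraskov-style k-nearest-neighbour estimator, per-residue and
    normalized inter-domain coupling scores, essential-dynamics principal
    component analysis, side-chain centre-of-mass salt-bridge monitors,
    atom-pair distance monitors, and seeded synthetic-trajectory
    generators with known statistical ground truth. Includes a
    configuration-driven pipeline reproducing a full analysis suite on
    any topology plus trajectory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
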