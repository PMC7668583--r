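Package: remdguide
Title: Contact-Guided Replica-Exchange Molecular Dynamics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for contact-guided replica-exchange molecular dynamics
    (REMD) of proteins: construction of residue-residue contact restraint
    sets at controlled true-positive rates, sigmoid bias potentials with
    engine-ready tabulated interaction files and topology patches,
    exponential REMD temperature-ladder generation with per-block step
    boosts and Metropolis exchange, a desk-scale C-alpha bead Langevin REMD
    simulator, and a trajectory evaluation suite (RMSD heatmaps, Global
    Distance Test scores, percentile significance tables, enrichment
    histograms, local-accuracy maps). Structures, contact lists, ladders
    and score series are tibbles throughout, with ggplot2 autoplot methods
    and broom-style tidiers.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
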