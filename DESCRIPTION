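Package: lmscreen
Title: Ligand-Based Virtual Screening with Levenberg-Marquardt Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-step ligand-based screening workflow: multitask target
    prediction with a feedforward neural network trained by a damped
    Levenberg-Marquardt loop, and fingerprint (Tanimoto) similarity search
    with neural-network hit prioritization. Includes a compact SMILES
    parser and hashed circular fingerprints, regression/classification
    evaluation metrics, post-docking bookkeeping (docking-score ranking,
    MM-GBSA-style binding free energies, mass-weighted RMSD and RMSF),
    and a synthetic benchmark generator that plants a structure-activity
    relationship around a seed scaffold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
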