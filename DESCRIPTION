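Package: dockrescore
Title: Rescoring Protein-Ligand Docking Poses with Vina Terms and Random Forests
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction and machine-learning rescoring of protein-ligand
    docking poses. Parses AutoDock PDBQT receptors and multi-model ligand pose
    files, computes the five AutoDock Vina interaction terms (inter- and
    intra-molecular) plus the rotatable-bond count, and the 36 elemental
    occurrence-count contact features of RF-Score. Provides four scoring models
    (fixed-weight Vina, multiple linear regression on Vina terms with a rotor
    penalty grid search, and random-forest regression on Vina terms alone or
    combined with contact features), six pose-selection schemes for assembling
    per-complex feature vectors from docked pose ensembles, the standard
    evaluation metrics (RMSE, residual SD, Pearson and Spearman correlation,
    heavy-atom RMSD without superposition), and a seeded synthetic-complex
    generator so the whole pipeline can be exercised without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
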