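Package: fabpocket
Title: Prediction of Fatty Acid-Binding Pockets on Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects candidate cavities on protein structures as clustered
    alpha spheres (spheres tangent to four atoms that contain no atom
    center), converts each pocket into a fixed-order descriptor vector
    combining geometry, physicochemistry and backbone secondary-structure
    composition, and classifies pockets as fatty-acid binding or not with a
    multilayer-perceptron trained on curated positive/negative pocket sets
    under stratified 5-fold cross-validation. Two independently trained
    models are combined by a strict consensus rule (score > 0.5 under both),
    and a false-positive-rate estimator scores pockets from a negative pool
    of ligand-bound structures whose ligands are not fatty acids. A
    synthetic-structure and feature-matrix generator lets the whole pipeline
    run without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
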