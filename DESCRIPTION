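Package: boneSCT
Title: Synthetic CT from Dual-Echo MR for Bone Metastases: Phantom
    Simulation, Patch-Based Translation and Metric Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for assessing MRI-based synthetic CT
    (sCT) of metastatic pelvic and femoral bone. Generates paired dual-echo
    spoiled gradient-echo MR and CT digital phantoms carrying osteolytic,
    osteoblastic or mixed lesions; normalizes intensities and extracts
    3D patches; rigidly initializes CT-to-MR alignment with an iterative
    closest point algorithm on bone surfaces; trains a 3D patch-based
    UNet-like MR-to-CT regression network under leave-one-out
    cross-validation; and scores sCT against CT with mean absolute and mean
    signed HU differences, 150-HU bone extraction, Dice overlap and
    directed root-mean-square surface distance (with a 3-cm lesion margin),
    summarized per cohort as mean and sample standard deviation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
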