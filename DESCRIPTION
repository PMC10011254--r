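Package: petconseg
Title: Consensus Contouring and Robustness Evaluation for PET Tumor Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and evaluation framework for consensus contouring in
    18F-FDG PET tumor delineation. Generates synthetic heterogeneous lung
    lesions with uptake derived from the two-tissue compartment FDG kinetic
    model, optional respiratory-motion averaging, and PET-like image
    degradation; segments them with four automatic methods (region-based
    active contour, affinity propagation, contrast-oriented thresholding,
    and 41%-of-maximum thresholding) under two initial-mask conditions;
    fuses the results into majority-vote consensus contours; and quantifies
    accuracy (relative volume error, Dice similarity coefficient) and
    test-retest robustness with nonparametric statistics (Friedman test,
    post hoc Wilcoxon signed-rank with Bonferroni adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    Rcpp,
    deSolve,
    jsonlite,
    RNifti,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
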