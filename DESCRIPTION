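Package: densecranio
Title: Dense Quasi-Landmark Phenotyping of Craniofacial Bone Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated dense 3D phenotyping of craniofacial bone surfaces.
    Builds a quasi-landmark template mask, non-rigidly registers it to
    target skull meshes (similarity initialisation from sparse landmarks,
    rigid iterative closest point, annealed smoothed-displacement non-rigid
    adaptation), transfers sparse anatomical landmarks through barycentric
    encoding with leave-one-out evaluation, separates true from gap
    quasi-landmarks by normal-ray distance, and computes the reliability
    and accuracy statistics of observer studies (RMS dispersion,
    two-way intraclass correlation, Bland-Altman agreement, centroid-size
    ANOVA, Procrustes shape-variance decomposition). Includes a synthetic
    skull-like mesh generator with known ground truth so the whole
    pipeline is testable without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
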