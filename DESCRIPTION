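Package: bonequiv
Title: Geometric Equivalence Assessment of CT-Derived 3D Bone Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for assessing whether two computed-tomography
    modalities (e.g. weight-bearing cone-beam CT and multidetector CT)
    produce geometrically equivalent 3D bone models. Extracts triangle
    meshes from binary bone segmentations with marching cubes, rigidly
    aligns paired models with the iterative closest point algorithm,
    computes signed vertex-to-surface distances inside focused regions
    of interest, and evaluates equivalence with summary intervals,
    normality tests, one-sample TOST with a clinical margin, and
    noncentral-t power analysis. Includes a synthetic knee-bone phantom
    generator with known ground truth for end-to-end validation, and a
    packaged fixture of published per-bone mean surface distances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
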