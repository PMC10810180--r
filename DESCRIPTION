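Package: decreg
Title: Decision Region Composition Analysis for Image Classifier Generalizability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Audits the generalizability of binary image classifiers by probing
    the composition of their decision space near the data manifold. Virtual
    images are synthesized by barycentric interpolation on planes spanned by
    triplets of same-subgroup images, classified, and summarized as per-class
    decision-region fractions. The package detects "preferred" output classes,
    evaluates behavior under population shift and cross-reactivity (samples
    whose true class is absent from the model outputs), calibrates
    equal-error-rate decision thresholds, builds patient-stratified data
    partitions, and ships a synthetic cohort generator with analytic linear
    scorers and an exact triangle-clipping composition oracle for verification.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
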