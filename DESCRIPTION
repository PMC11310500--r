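Package: contourQA
Title: Quantitative Evaluation and Knowledge-Based QA of Organ Auto-Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates automatic organ segmentations on CT against ground-truth
    contours using six volumetric overlap metrics computed inside the union
    bounding box (Dice, Jaccard, true positive rate, true negative rate,
    positive predictive value, Rand index) and seven Hausdorff-family surface
    distance metrics in millimetres. Provides a knowledge-based quality
    assurance tool that scores new contours by comparing the kernel density
    estimate of their Hounsfield-unit distribution against a per-organ
    reference baseline with plus/minus two standard deviation bounds, cohort
    aggregation with paired significance tests, and a deterministic synthetic
    CT phantom generator for end-to-end testing without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
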