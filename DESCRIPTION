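Package: stainmil
Title: Stain-Robust Multiple-Instance Classification of Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A classification framework for H&E histopathology images (Normal
    vs. oral squamous cell carcinoma) that suppresses staining bias in feature
    space and aggregates patch-level evidence with a spatially structured
    graph-transformer head. Provides a pluggable token backbone, a
    morphology-dominant encoder with a per-token sigmoid gate over stain and
    morphology feature components, a classifier head with radius-based dual
    topology and content-driven dynamic adjacency, class-imbalance-aware
    training with hand-derived analytic gradients, a deterministic synthetic
    stain-shift image generator, and tie-aware evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    tibble,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
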