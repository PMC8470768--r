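Package: layerfuse
Title: Deep-Layer Descriptors and SVM Ensembles for Biological Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic vision pipeline for biological image classification:
    activation tensors are extracted from inner and final layers of a
    convolutional backbone, compressed to fixed-length descriptors by
    per-channel or global discrete cosine transform, principal component
    analysis, chi-square feature selection, uniform local binary patterns,
    deep co-occurrence pooling, global entropy pooling, or global
    mean-thresholding pooling, and one radial-basis SVM is trained per layer.
    Per-layer score matrices are fused by a normalized sum rule, with named
    ensemble recipes, "-2" variants that drop the two deepest layers, and
    sequential forward floating selection of classifier subsets. Includes a
    seeded synthetic texture-image generator and a small fixture CNN so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    png,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
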