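Package: msfs
Title: Texture-Feature Extraction and Hybrid Sea-Horse/Sine-Cosine Feature
    Selection for MS Detection in Brain MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting multiple sclerosis from 2-D grayscale
    brain-slice images via texture analysis and wrapper feature selection.
    Extracts a 286-dimensional texture descriptor (first-order histogram
    statistics, gray-level co-occurrence matrix features at four
    orientations, and a 256-bin local binary pattern histogram), selects
    discriminative features with a hybrid sea-horse-optimizer /
    sine-cosine-algorithm (SHOSCA) binary wrapper driven by a KNN
    classification-error fitness, and evaluates competing optimizers with a
    repeated-run protocol and Friedman ranking. Includes synthetic image and
    feature-table generators so the whole pipeline is testable without
    clinical data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    jsonlite,
    jpeg,
    optparse,
    png,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
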