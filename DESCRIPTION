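Package: hfusqa
Title: Quality Assessment of High-Frequency Ultrasound Skin Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated image quality assessment for high-frequency ultrasound
    (HFUS) recordings of the skin. Fuses the binary suitability labels of three
    expert annotators into four-group consensus labels, quantifies
    inter/intra-observer agreement with unweighted Cohen's kappa, trains
    convolutional image classifiers (a compact in-package engine with VGG16,
    DenseNet-201 and a small desk-scale backbone), combines per-expert model
    scores with majority voting or a Mamdani fuzzy inference system, and
    evaluates the eight resulting processing paths under 5-fold
    cross-validation. Includes a synthetic HFUS frame generator with three
    simulated annotators so the whole pipeline is testable without the
    clinical dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
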