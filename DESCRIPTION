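Package: quanvolve
Title: Quanvolutional Feature Extraction and Hybrid Quantum-Classical
    Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact statevector simulation of a four-qubit quanvolutional
    feature extractor for grayscale images, with selectable CNOT or CZ
    entangling layers, joint training of quantum rotation angles
    (parameter-shift rule) and a small classical convolutional head,
    stratified k-fold cross-validated evaluation with confidence-interval
    reporting, a native-gate (ECR/SX/RZ) decomposition and dephasing-error
    propagation toolkit for comparing the two entanglers at the hardware
    level, and a seeded generator of synthetic fruit-quality image
    datasets for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    broom,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
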