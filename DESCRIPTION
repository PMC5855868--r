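Package: wkfda
Title: Weighted-Kernel Fisher Discriminant Analysis for Chemosensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction for electronic-nose (chemosensor-array)
    classification via kernel Fisher discriminant analysis with a weighted
    composite of Mercer kernels whose mixing weights and base-kernel
    parameters are tuned by quantum-behaved particle swarm optimization
    (QPSO).  Includes the standard linear baselines (PCA, locality
    preserving projections, Fisher discriminant analysis), repeated
    stratified hold-out and fixed-batch transfer evaluation protocols with
    a support-vector classifier, seeded generators of synthetic sensor-array
    responses (wound-headspace-like and drifting inflammable-gas-like
    designs), and delimited-text I/O for labeled feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
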