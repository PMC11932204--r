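Package: MINNTarget
Title: MicroRNA Target-Site Detection with Duplex-Structure Features and a
    Multi-Input Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects microRNA target sites in 3'UTR sequences from learned
    base-pairing preferences. A single-neuron network trained on 24,450 binary
    single/double/triple canonical base-pair features yields position- and
    type-specific pairing weights; a dynamic-programming duplex predictor
    maximizes total structure weight and evaluates nearest-neighbor (Turner
    2004) free energies of every optimal substructure; four derived 25x25
    matrices (predicted structure, DP scores, substructure free energies, and
    rRNA-derived base-pair probabilities) feed a four-branch convolutional
    classifier. Includes negative-sample generation from 3'UTR windows,
    stratified splitting, a synthetic corpus generator, precision-recall
    evaluation with threshold optimization, and bootstrap model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
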