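Package: tonalschema
Title: Connectionist Simulation of Musical Tonal Schema Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates how sensitivity to musical scale membership and to
    implied harmony emerges in a multilayer perceptron that learns to
    identify the key of monophonic tone-chroma melodies by mere exposure.
    Provides a synthetic diatonic melody corpus generator with
    transposition augmentation, positional pitch-class encoding, a
    backpropagation-trained network with periodic checkpointing, a
    three-condition test battery probing scale and harmony sensitivity,
    and repeated-measures analyses of the resulting learning trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
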