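Package: stpam
Title: Semi-Tensor Product Associative Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An associative memory model built on the semi-tensor product
    (STP) of matrices. Bipolar patterns are encoded as canonical basis
    vectors of a 2^n-dimensional space, where a sparse diagonal memory
    matrix stores and exactly recalls up to 2^n patterns. Corrupted
    probes are associated to stored patterns through an on-demand,
    inverse-Hamming-distance column update controlled by a bit error
    control (BEC) parameter, yielding a probability distribution over
    candidate patterns. A classical discrete Hopfield network with
    Hebbian outer-product weights is included as a capacity baseline,
    together with pattern file input/output, a seeded pattern and
    corruption generator, Monte-Carlo capacity experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
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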