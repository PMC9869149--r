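Package: hdmem
Title: Hypervector Memories: Superposition Vectors and Sparse Distributed Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the capacity and cost of hyperdimensional
    (vector-symbolic) memories. Implements two superposition-vector memories
    (binarized with Hamming readout, and integer-counter with dot-product
    readout) and four Sparse Distributed Memory readout variants, the
    encoding of finite-state automata into either memory family, analytic
    recall-error predictors for every variant, dimension search to a target
    error rate, and the storage and operation-count accounting used to
    compare the memory families. All inputs are generated internally from
    seeded random codebooks and automata; results are returned as plain
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
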