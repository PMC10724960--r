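Package: cssmo
Title: Hybrid Cuckoo Search and Spider Monkey Optimization for Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper gene selection for high-dimensional expression data
    (microarray and RNA-seq count-derived matrices) built around a hybrid of
    cuckoo search and spider monkey optimization. Expression matrices are
    prefiltered by greedy minimum-redundancy maximum-relevance (mRMR) ranking
    on discretized values, then a swarm of continuous positions in the unit
    hypercube searches for the gene subset maximizing leave-one-out
    cross-validation accuracy. Includes standalone cuckoo-search and
    spider-monkey baselines, a deterministic k-nearest-neighbour surrogate
    fitness, a compact convolutional network classifier for final evaluation,
    a synthetic expression-data generator with planted informative genes for
    benchmarking, and confusion-matrix/precision/recall/F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
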