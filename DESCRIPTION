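Package: pathXtalk
Title: Crosstalk Analysis of Gene Sets on Molecular Interaction Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the alteration of the interconnectivity (crosstalk)
    between pairs of gene sets -- intra-cellular pathways, cell-type marker
    sets, or both -- from gene-level alteration weights and a gene-centric
    molecular interaction network. The crosstalk score is the bilinear form
    of the two weight vectors over the binary adjacency matrix; its
    significance is assessed with two complementary degree-binned label
    permutation null models (one randomising interactions, one randomising
    weights) whose empirical probabilities are combined with Fisher's product
    method. Mediator genes are ranked by crosstalk diversity and interactor
    diversity. Includes readers and writers for GMT gene sets, scored edge
    lists and weight tables, a weighting scheme for differential-expression
    results, a synthetic-data generator with planted crosstalks, and
    end-to-end pipelines for intra-cellular, inter-cellular and integrated
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
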