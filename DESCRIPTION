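Package: fragchain
Title: Local Fragment Chaining with Linear and Sum-of-Pair Gap Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sparse dynamic-programming chainer for scored local match
    fragments, such as BLAST hits between a query and a database sequence.
    Finds best-scoring local chains of non-overlapping, colinearly ordered
    fragments under either a linear gap cost model or a sum-of-pair gap
    cost model, using a line sweep over fragment start and end points with
    range-maximum-query structures (dominance staircases and a range tree)
    to locate optimal predecessors. Includes an output-preserving
    clustering pre-pass that splits fragment sets at database gaps too
    expensive to bridge, readers for BLAST tabular and a generic fragment
    TSV format, chain report and BED writers, and synthetic fragment
    generators for benchmarking and for scattered-homology scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
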