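Package: dbgcrf
Title: Node and Arc Multiplicity Inference in de Bruijn Graphs Using
    Conditional Random Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the multiplicity (genomic copy number) of every node and
    arc of a compacted de Bruijn graph built from short-read sequencing data.
    Per-element coverage evidence is modelled with a mixture of negative
    binomial distributions and combined with conservation-of-flow constraints
    in a conditional random field, whose marginals are computed exactly by
    log-space variable elimination.  Mixture parameters are estimated by
    expectation-maximisation with method-of-moments updates.  Includes a
    desk-scale graph builder with GFA1 interoperability, quality-weighted
    (q-mer) counting, a seeded genome/read simulator with ground-truth
    multiplicity labels, and an evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
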