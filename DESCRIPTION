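Package: softmem
Title: Reservoir Computing Analysis of Soft Memory in Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the structure of transcriptional
    regulatory networks determines their capacity to hold transient
    ("soft") memory when treated as reservoir computers.  Provides a
    signed-digraph data model with edge-list input/output and
    recurrent-core extraction, generators of random signed digraphs
    matching the connectivity statistics of the Escherichia coli
    transcriptional network, discrete-time tanh reservoir dynamics with
    spectral-radius normalisation, ridge-regression readouts, the
    short-term memory capacity, 10th-order NARMA and delayed-AND
    benchmark tasks, maximum Lyapunov exponent estimation by
    two-trajectory renormalisation, a census of memory motifs
    (self-loops, mutual regulation, feedforward loops) with
    randomised-ensemble z-scores, and sub-reservoir sampling by iterated
    node removal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
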