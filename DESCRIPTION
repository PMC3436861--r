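Package: motifbounds
Title: False-Positive Bounds and Null Simulations for OOPS DNA Motif
    Finding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic large-deviations (Sanov) bounds on the information
    content of false-positive motifs in one-occurrence-per-sequence
    (OOPS) de novo DNA motif discovery, exact small-sample p-values for
    motif information content under an i.i.d. background, a Gibbs
    site-sampler motif finder, and a Monte-Carlo simulation framework
    that validates the bounds on random sequences.  Includes closed-form
    design queries relating dataset size (number of sequences, sequence
    length, motif width) to the expected strength of chance motifs, and
    readers for FASTA sequence sets and JASPAR-style position frequency
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
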