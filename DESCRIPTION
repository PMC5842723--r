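Package: msaparam
Title: Theory-Driven Gap-Penalty and Substitution-Matrix Selection for
    Multiple Sequence Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chooses the parameters of the sum-of-pairs objective for
    protein multiple sequence alignment from statistics of the unaligned
    family itself. Computes family statistics (sequence count, length
    range, mean pairwise identity, expected match and gap counts), tests
    whether a BLOSUM substitution matrix is rational for a family,
    estimates affine gap-open and gap-extension penalties from a closed
    formula with tunable weight coefficients, scores alignments with the
    sum-of-pairs objective and the SPS benchmark metric, and ships a
    small progressive Gotoh aligner, a synthetic protein-family
    simulator and a parameter-sweep harness so the estimated parameters
    can be exercised end to end without external aligner binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
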