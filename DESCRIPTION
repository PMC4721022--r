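Package: rsdc
Title: Relative Simplicity Scoring and Direct Classification of
    Gene-Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Information-theoretic feature scoring and multi-class
    classification for small-sample, high-dimensional gene-expression
    matrices.  Implements the relative simplicity (RS) score of 2 x r
    contingency tables, an integrated gene ranking that combines vertical
    (per-gene threshold) and horizontal (within-sample order) pair-wise
    comparisons, forward informative-gene selection driven by
    leave-one-out Matthews correlation, and a transductive direct
    classifier with one-versus-rest selection and paired-votes
    multi-class prediction.  Entropy- and chi-square-based score
    backends are provided as drop-in comparators, together with a seeded
    generator of pattern-planted synthetic expression datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
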