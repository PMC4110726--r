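Package: apforest
Title: Exact Metric-Space k-mer Indexing and Ensemble Read Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds an exact metric-space index over genomic k-mers, the
    adaptive projection forest: a multi-pivot excluded-middle vantage-point
    forest supporting range queries with a zero-false-negative guarantee
    under Hamming (or any metric) distance. On top of the index it provides
    a seed-and-extend short-read mapper and a two-stage ensemble pipeline
    that rescues low-confidence alignments (by SAM MAPQ) from a heuristic
    first-stage aligner, together with a synthetic genome and read
    simulator with a scalable position-dependent substitution-error
    profile, truth tracking, and a mapping-accuracy evaluator that
    distinguishes incorrect from unrecoverable placements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
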