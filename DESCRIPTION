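Package: gapdelta
Title: Detection of Sample-Specific Sequences from Read-Coverage Gaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic sequences present in one sample's assembly but
    absent from another sample's short reads, the signature of recent
    transposable-element invasions. Reads are aligned locally to the assembly,
    per-base depth is computed, zero-coverage gaps are called, merged and
    length-filtered, scored with a flanking-coverage bias statistic, clustered
    by pairwise sequence similarity, and summarised as majority-rule consensus
    sequences, without requiring a repeat library. Includes a built-in
    seed-and-extend local read mapper, a simulator of template genomes with
    multi-copy insertions and uniform, random or ancient-DNA-style read sets,
    and a validation harness reporting true/false positive counts and
    consensus accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
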