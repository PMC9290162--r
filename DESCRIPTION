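Package: lramp
Title: Long-Read Amplicon Mutation Profiling for BCR-ABL1 Resistance Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of high-accuracy long-read amplicon sequencing
    for tyrosine-kinase-inhibitor resistance mutation screening in the
    BCR-ABL1 fusion transcript. Filters reads by anchored primer matching,
    assigns the dominant transcript isoform as reference, aligns reads with a
    banded semi-global affine-gap aligner, enforces minimum-coverage quality
    control, calls known and de novo nucleotide substitutions with per-read
    codon-level variant allele frequencies, resolves the clonal composition of
    co-occurring mutations by exact per-read phasing, and reports
    method-versus-method concordance. Includes a synthetic amplicon read
    simulator with known clone structure so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
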