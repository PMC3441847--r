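Package: promfam
Title: Transcription Factor Binding Site Family Overrepresentation in
    Subtype-Specific Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: In-silico analysis of promoter regulation across expression
    subtypes. Scans promoter windows (-500..+100 bp around the TSS) with
    position weight matrices, aggregates matrix-level matches into TFBS
    matrix families, and measures family overrepresentation against a
    resampled genomic-promoter background via a fold factor and a
    continuity-corrected z-score. Ranks families by their multivariate
    distance (Hotelling's T2) across subtypes using centered PCA of the
    family-by-subtype fold-factor matrix, mines shared ordered-motif
    promoter frameworks with distance constraints, and correlates family
    overrepresentation with subtype-specific transcription factor
    expression. Includes a synthetic-data generator with a ground-truth
    ledger and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
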