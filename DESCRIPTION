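Package: editscape
Title: Genome-Wide A-to-I RNA Editing Analysis for Paired Tumor and
    Normal Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls A-to-I RNA editing sites from matched RNA and DNA
    per-site base-count tables, applies a high-confidence filter cascade
    (base quality, depth, editing-level range, multi-allelic, DNA-variant
    and SNP removal), classifies sites into shared, tumor-specific and
    normal-specific differential-editing groups with pooled Fisher exact
    tests, profiles the sequence context around edited adenosines,
    associates editing with ADAR deaminase expression, scans editing
    frequencies for tumor/normal differentiation with a Weir-Cockerham
    F_ST estimator, and intersects differentially edited sites with
    differential-expression and alternative-splicing tables. Ships a
    synthetic-data generator that plants editing sites, SNP and DNA-variant
    confounders, ADAR-coupled global editing activity and motif-biased
    sequence context with a complete ground-truth set, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
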