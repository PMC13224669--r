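Package: tdrsv
Title: Tissue-Specific Gene Dosage Impact of Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tissue-specific gene-dosage impact of structural
    variants (SVs) through the Transcript Disruption Ratio (TDR): the fraction
    of a gene's total transcript expression (TPM) in a tissue contributed by
    transcripts whose coding exons are disrupted by a variant. Around the
    metric the package implements a tiered SV quality-control workflow
    (exclusion regions, short-SV re-genotype confirmation, reciprocal-overlap
    corroboration of medium and long copy-number variants), construction of a
    multi-ancestry background allele-frequency database by same-type
    reciprocal-overlap clustering with maximum-AF assignment, a staged
    candidate-pathogenic-SV prioritization cascade (rarity, dosage class,
    TDR and disease gene lists, inheritance and dosage-sensitivity
    consistency), and the population statistics used to validate the metric
    (expression outlier calling, carrier-outlier enrichment odds ratios,
    TDR-expression correlation, TSS-distance enrichment). A deterministic
    synthetic-data generator produces every input format the toolkit consumes,
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
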