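Package: snpIsomiR
Title: Individual SNP-Aware Pre-miRNA Processing-Site Prediction and IsomiR Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate isoform microRNAs (isomiRs) arising from an
    individual's single nucleotide polymorphisms (SNPs) inside precursor miRNA
    hairpins. SNPs from a per-sample VCF are placed at strand-resolved positions
    within annotated pre-miRNA hairpins, all combinatorial SNP-substituted
    precursor sequences are enumerated, and the four Drosha/Dicer processing
    sites (P5_5, P5_3, P3_5, P3_3) are predicted with per-site support vector
    machine classifiers trained on a 115-dimensional secondary-structure and
    duplex feature set. Mature sequences induced by variant precursors that fall
    outside the canonical candidate set are called isomiRs and validated by
    exact search in small-RNA sequencing reads. A deterministic synthetic-data
    generator produces hairpins with planted processing sites, matching VCFs and
    read sets for end-to-end benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    e1071,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: ViennaRNA RNAfold (optional folding backend)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
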