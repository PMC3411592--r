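Package: exopipe
Title: Exome Sequencing Read Preprocessing, Alignment Filtering,
    Capture Metrics and Variant Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of an exome
    sequencing workflow that sit between the standard external engines
    (aligner, realigner, variant caller, annotation databases): FASTQ
    dialect detection and quality-encoding conversion (Sanger, Solexa,
    Illumina 1.3+, ABI SOLiD csfasta/qual), read trimming and filtering
    with per-stage accounting, alignment filtering (unmapped,
    properly-paired, coordinate-based PCR-duplicate marking, on-target
    selection), exome capture metrics (per-exon fold coverage, capture
    specificity, expected duplicates by chance, insert-size metrics),
    variant post-processing (zygosity splitting of SNPs and small
    indels, Ti/Tv ratio, annotation-table merging, summaries), and a
    multi-section summary report.  A seeded synthetic-data generator
    plants recoverable ground truth (filter-failure counts, duplicate
    rates, on-target fractions, Ti/Tv, zygosity fractions) so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
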