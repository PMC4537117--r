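Package: paneldx
Title: Targeted Gene Panel Diagnostics: Coverage QC, Dosage Calling and
    Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis for targeted next-generation sequencing
    diagnostic panels. Implements per-sample capture statistics and quality
    gates, exon-level copy-number calling by depth normalization against
    in-batch controls, chromosome-level dosage analysis (aneuploidy,
    segmental microdeletion/microduplication, sex inference) from on-target
    read counts, candidate-gene variant prioritization under Mendelian
    inheritance models with trio segregation, genotype-concordance and
    replicate-stability statistics, an HGVS-style coding-variant parser and
    classifier, and a synthetic-data generator (depth matrices, chromosome
    counts, trio call sets, platform-comparison genotype tables) so that the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
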