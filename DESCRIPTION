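Package: cypscope
Title: Polymorphic Cytochrome P450 Catalogs, Population Allele Frequencies
    and Tissue Expression Maps
Version: 0.1.0
Authors@R:
    person("cypscope", "developers", email = "cypscope@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying polymorphic cytochrome P450 (CYP) drug
    metabolizing enzymes. Provides dictionary-based relation mining of
    plain-text abstracts for (CYP, ethnicity, frequency, effect) tuples
    with distance-rule scoring; a curated Caucasian star-allele frequency
    catalog with the one-percent pharmacogenetic polymorphism filter;
    cohort allele-frequency computation from diploid VCF genotypes with a
    non-synonymous one-percent filter, star-allele presence calling and
    novel-variant flagging; probe-to-gene aggregation with per-gene tissue
    z-scores and fold-threshold body-map calls; and seed-deterministic
    synthetic-data generators with ground-truth ledgers so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
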