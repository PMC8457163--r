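Package: celldmr
Title: Cell-Type-Specific Promoter Methylation Analysis with
    Resampling-Based GWAS Overlap Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for case-control analysis of promoter tiling-array DNA
    methylation-enrichment data from sorted brain nuclei. Calls
    differentially methylated regions (DMRs) per cell type with a windowed
    Stouffer-combined Welch-t statistic under an analytic or
    label-permutation null, summarises DMR-associated gene sharing between
    neuronal and nonneuronal fractions, integrates matched expression data
    (reliability and brain-pH filtering, per-probe Welch tests), and tests
    enrichment or depletion of DMR sets in GWAS loci by promoter-based
    random sampling with empirical p-values. Includes a synthetic-data
    generator with planted DMRs and ground-truth tables for calibration and
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
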