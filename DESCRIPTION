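Package: cistromics
Title: Cistrome Integration, Matched-Null Co-Occupancy Testing, and
    Allelic Imbalance at Regulatory Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating transcription-factor ChIP-seq peak sets
    (cistromes) with differential-expression data and regulatory-variant
    annotation. Implements a covariate-matched permutation test for cistrome
    co-occupancy in which random region sets are constrained to open
    chromatin and matched jointly on GC content and distance-to-TSS
    profiles; nearest-TSS peak-to-gene assignment and target-set shift
    tests; LD-based tag-SNP expansion and SNP-by-peak intersection with
    allele-aware position weight matrix scoring; and an allelic-imbalance
    test at heterozygous regulatory SNPs based on per-donor exact binomial
    tests combined by Fisher's method. Ships a seeded synthetic-data
    generator with planted ground truth (genomes with GC strata, peak sets
    with a controllable planted overlap fraction, DE tables with planted
    shifts, LD-block genotypes, and allele-specific read pileups) so that
    every stage of the pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
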