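Package: hapeqtl
Title: Multi-Founder Haplotype eQTL Mapping with Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expression quantitative trait locus (eQTL) mapping for
    multi-founder recombinant inbred line panels genotyped as per-marker
    founder-origin probabilities. Implements LOD-score genome scans by
    regression on additive founder probabilities, gene-wise permutation
    significance thresholds, Storey q-values, cis/trans classification on
    the genetic map, condition-specific trans-eQTL hotspot detection with a
    band-permutation null and conditional-LOD merging of adjacent peaks,
    surrogate variable estimation, and a paired genotype-by-environment
    interaction scan. A synthetic-data generator emulates founder-mosaic
    RIL genomes and paired two-condition expression with planted effects so
    every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    ggplot2,
    rtracklayer,
    GenomicRanges,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
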