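# hapeqtl

Expression QTL mapping for multi-founder recombinant inbred line (RIL)
panels — the experimental design in which every line is a homozygous mosaic
of K sequenced founder strains and genotypes arrive as per-marker
**founder-origin probabilities** rather than SNP calls. The package is aimed
at studies that assay each line under two paired conditions (e.g. control vs.
a toxicant exposure) and ask not only *where* expression is genetically
controlled, but *which* of that control appears or disappears with the
exposure.

## What it computes

For gene expression `y` over RILs and founder probabilities `G_i` at a
marker, the core scan compares

    H0:  y = mu + e
    H1:  y = mu + sum_i G_i * beta_i + e        (i = 1..K founders)

and scores association with the Gaussian likelihood-ratio identity

    LOD = (n/2) * log10(RSS0 / RSS1).

On top of that single primitive the package provides:

* **gene-wise permutation thresholds** — per gene, the genome-wide maximum
  LOD over shuffled expression builds an empirical null; `p` is the fraction
  of permutation maxima at or above the observed LOD, and Storey q-values
  convert the p-values to FDR;
* **cis/trans classification** — a significant association is *cis* when the
  marker lies within 1 cM (inclusive) of the gene midpoint on the genetic
  map, *trans* otherwise, with gene map positions interpolated from the
  marker map;
* **condition specificity** — shared / ctrl-specific / trt-specific labels
  per gene and class from the two independent condition scans;
* **trans-eQTL hotspot detection** — per-marker counts of distant associated
  genes, a band-permutation null that preserves each gene's hit count,
  permutation hotspot p-values, and conditional-LOD merging of peaks that
  are not genetically separable, reported as start/peak/end regions;
* **surrogate variables + G×E scan** — residual-SVD surrogate variables with
  parallel-analysis dimension selection, and an interaction scan
  (`H1` adds `sum_i G_i * E`) with within-pair condition-label permutation;
* **a synthetic-data generator** — founder-mosaic genomes (junction process
  on the cM axis, ~1% residual heterozygosity, soft probabilities with 0.5%
  error mass) and paired two-condition expression with planted cis, hotspot,
  treatment, and interaction effects, recorded in a truth table so every
  stage is testable against known ground truth.

All tabular formats are plain TSV (marker map, long-format genotype
probabilities, `<ril>__<ctrl|trt>` expression columns, gene annotation,
truth tables) with lossless round-trips at 9 significant digits.

## Worked example

Simulate a panel with one treated-only master locus trans-regulating 30
genes, scan the treated condition, and detect the hotspot:

```r
library(hapeqtl)

sim <- simulate_scenario("hotspot_trt", seed = 1)
xn  <- quantile_normalize_two_pass(sim$expression)

scan_trt <- scan_condition(xn, sim$genotypes, "trt", n_perm = 200, seed = 2)
hits <- classify_cis_trans(significant_hits(scan_trt), sim$annotation, sim$map)
table(hits$class)
#> trans
#>   155

hs <- detect_hotspots(scan_trt, sim$annotation, sim$genotypes, xn,
                      n_perm = 1000, seed = 3)
hs$hotspots[, c("chrom", "start_bp", "peak_bp", "end_bp", "n_genes", "p")]
#>   chrom start_bp peak_bp end_bp n_genes p
#> 1    2L   170000  200000 280000      12 0

seg <- founder_segregation_test(xn, strsplit(hs$hotspots$genes[1], ",")[[1]],
                                sim$genotypes, hs$hotspots$peak_marker[1],
                                condition = "trt")
sprintf("founder segregation at the peak: ANOVA p = %.2g", seg$p)
#> "founder segregation at the peak: ANOVA p = 1.5e-09"
```

The detected region peaks exactly at the planted master marker
(`2L_200000`): 12 distant genes are associated at the peak at nominal
p ≤ 0.05 — far more than the band-permutation null ever produces (hotspot
p = 0) — and the mean expression of the associated genes segregates strongly
by the founder each RIL carries at the peak. The same fixture's control
scan yields no hotspot at that locus, reproducing the designed
treatment-specificity.

The `analysis/` directory holds numbered drivers
(`01_simulate.R` … `06_report.R`) that run the same pipeline as a narrated
sequence on the `mixed` scenario and write every intermediate table under
`results/`; `run_pipeline()` does the same in one call.

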