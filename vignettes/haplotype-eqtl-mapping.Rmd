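---
title: "Multi-founder haplotype eQTL mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-founder haplotype eQTL mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hapeqtl maps expression quantitative trait loci (eQTLs) in panels of
recombinant inbred lines (RILs) descended from several sequenced founder
strains, where genotypes are delivered not as SNP calls but as per-marker
*founder-origin probabilities*: at every 10-kb segment junction, each line
carries a probability vector over the K founders describing which parental
genome that segment descends from. The package covers the full analysis
sequence for a paired two-condition design (each RIL assayed under a control
and a treated condition): normalization, paired differential expression,
per-condition LOD genome scans with permutation thresholds, cis/trans
classification, condition-specific trans-eQTL hotspot detection, and a
genotype-by-environment (G×E) interaction scan with surrogate variables.
A synthetic-data generator mirrors the whole data-generating process so that
every stage can be verified against planted truth.

## The haplotype regression and the LOD score

For one gene and one marker, with $y_r$ the (normalized, log-scale)
expression of RIL $r$ and $G_{ri}$ the probability that RIL $r$ carries
founder $i$ at the marker, the scan compares

$$H_0: y = \mu + \varepsilon
  \qquad\text{vs.}\qquad
  H_1: y = \mu + \sum_{i=1}^{K} G_i \beta_i + \varepsilon,$$

an additive model in the founder dosages with Gaussian errors. Because the
probabilities sum to one, the design $[1, G_1, \dots, G_K]$ is rank-deficient
by one. Only the residual sum of squares is identified, and it is all the
method needs: the evidence for association is

$$\mathrm{LOD} = \frac{n}{2}\,\log_{10}\frac{\mathrm{RSS}_0}{\mathrm{RSS}_1},$$

the exact log10 Gaussian likelihood ratio with the variance profiled out.
`fit_founder_regression()` returns the minimum-norm coefficient solution (SVD
pseudo-inverse); the test suite verifies that dropping a founder column
instead changes nothing downstream of the RSS. Degenerate cases are defined,
not special-cased away: identical genotype rows give $\mathrm{RSS}_1 =
\mathrm{RSS}_0$ and LOD 0; an exact fit returns `Inf`; a constant response
gives LOD 0. Heterozygous residual genotypes need no special handling — they
are simply probability mass split between two founders, which the regression
consumes directly.

## Permutation significance

Expression is scanned against every marker, so per-gene significance must be
genome-wide. For each gene, the RIL labels of its expression vector are
shuffled (within one condition) and the *genome-wide maximum* LOD of the
shuffled scan is recorded; repeating this `n_perm` times gives the gene its
own max-LOD null, and

$$p(\text{gene}, m) \;=\; \frac{\#\{\text{permutation maxima} \ge
\mathrm{LOD}_{\text{obs}}(m)\}}{n_\text{perm}}.$$

The max-based null was chosen over a per-locus null because it controls the
per-gene genome-wide error rate that the downstream counting steps assume; a
per-locus mode remains available (`per_locus_null = TRUE`). The plug-in
estimator (which can return exactly 0) is the default; `smooth = TRUE`
switches to $(1+b)/(1+B)$. Both condition scans are run independently, and
specificity labels (shared / ctrl-specific / trt-specific) are assigned at
the gene level per class. p-values are converted to q-values with Storey's
estimator ($\pi_0$ from a cubic smoothing spline over
$\lambda = 0.05, \dots, 0.95$, evaluated at $\lambda = 0.95$, with a
fallback to $\pi_0 = 1$ for short vectors).

## cis versus trans

A significant (gene, marker) pair is *cis* when the marker lies within 1 cM
of the gene midpoint on the genetic map — inclusive at exactly 1.0 cM — and
*trans* otherwise; different chromosomes are infinitely distant. Gene
genetic positions are obtained by linear interpolation of the marker map in
bp → cM, clamped beyond the terminal markers, since RIL genotype resources
publish marker positions but not gene map positions. The 1 cM radius and the
chromosome set (`X, 2L, 2R, 3L, 3R` by default; the small fourth chromosome
is typically excluded from such panels for lack of marker information) are
configurable.

## Trans-eQTL hotspots

Individual trans effects are usually too weak to survive genome-wide
correction at realistic panel sizes; what is detectable is their
*aggregation*: a locus associated with many distant genes at the nominal
p ≤ 0.05 — a vertical band on the eQTL map. The hotspot stage:

1. builds the distant-hit indicator `D[marker, gene]` (eQTL p ≤ 0.05 **and**
   distance > 1 cM, so local signal never inflates a band);
2. counts associated genes per marker;
3. generates a band-permutation null: each gene's indicator row is
   independently re-placed across markers, preserving that gene's hit count.
   The null pools all per-marker counts across replicates (markers are
   exchangeable under the row permutation); a per-marker and a
   block-permutation mode (one shared marker permutation per replicate,
   preserving gene–gene correlation) are available as sensitivity flags. The
   independent-row default matches the counting procedure but is
   anti-conservative under strong co-expression — a documented limitation;
4. assigns `p(m)` = fraction of null counts ≥ observed count; candidates are
   markers with p ≤ 0.05;
5. merges candidate peaks that are not genetically separable.

Merging fits, for each pair of candidate peaks within 5 cM on a chromosome
and each gene associated with both, the joint two-locus model against the
single-locus model and takes the conditional LOD of one peak given the
other. The pair combines when the *median* conditional LOD across shared
genes falls below 1.5. Two deliberate choices here:

* **Symmetry.** Separability is a symmetric notion, so the test uses the
  smaller of the two orientations (B given A, A given B) — a shadow peak on
  either side of a true locus adds nothing beyond it.
* **Chance level.** Conditioning across $j$ founder junctions adds about
  $\min(j_\text{switching RILs}, K-1)$ free columns, so the conditional LOD
  has a chance level of roughly $\tfrac{n}{2}\log_{10}\!\big(\text{df}/(\text{df}-r)\big)$
  — about 1.9 at $n \approx 60\text{–}80$, $K = 8$ for peaks more than a
  couple of junctions apart. Merging at the 1.5 default therefore only ever
  combines tightly linked peaks; this is intended (distant peaks *are*
  separable at this threshold), but it means the merge radius is effectively
  set by linkage, not by the 5 cM window.

Each merged group is reported as one hotspot region: the peak is the member
with the most associated genes (ties to the leftmost), the region spans the
contiguous run of hotspot-significant markers around it, and regions are
flagged shared / ctrl-only / trt-only by cross-condition overlap.

## Surrogate variables and the G×E scan

Expression heterogeneity is absorbed by surrogate variables: the expression
matrix is residualized against the known design (treatment, optionally RIL)
and the leading left singular vectors of the residual matrix are the
surrogates. With `k = "auto"` the dimension is chosen by parallel analysis
against structureless Gaussian matrices of the same size, drawn at the
df-corrected residual noise scale and projected into the residual subspace;
a component is kept while its singular value exceeds the null's 95th
percentile. We deliberately do *not* build the null by permuting the
observed residuals: permutation draws are conditionally concentrated around
the observed matrix, which in measurement kept a spurious first component in
15–33% of pure-noise runs; the parametric null restores the nominal ~5%.

The interaction scan then compares, over both conditions jointly,

$$H_0: y = \mu + S + \textstyle\sum_i G_i + E + \varepsilon
  \qquad\text{vs.}\qquad
  H_1: H_0 + \textstyle\sum_i G_i E,$$

with $E$ the treatment indicator and $S$ the surrogates, using the same
$\frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ statistic (the
founder blocks are rank-deficient by at least two; again only RSS matters).
Significance uses within-pair condition-label permutation — each RIL's two
samples may swap labels, preserving genotype and pairing exactly — with the
genome-wide maximum interaction LOD per replicate. The scan is invariant to
which condition is called control.

## Normalization and differential expression

Quantile normalization is two-pass: samples are normalized to the average
empirical distribution across samples, then the same procedure is applied
gene-wise. Ties receive the mean of their tied target quantiles, keeping the
operator permutation-invariant. After pass 1 every sample carries an
identical value multiset (an exact property, tested); the full two-pass
operator, however, is **only approximately idempotent** — the gene-wise pass
rearranges values so a second application moves them again, by an amount
that shrinks with the gene count but does not vanish. This is a property of
the operator itself, worth knowing before comparing repeated runs.

Differential expression fits `Y ~ treatment + RIL` by ordinary least
squares, which for complete pairs is exactly the paired t-test (verified
against `t.test(paired = TRUE)` to 1e-10); the treatment coefficient is the
log2 fold change with the treated-minus-control sign convention.

## What the simulator emulates — and what it does not

`simulate_ril_genotypes()` builds each RIL chromosome as a junction process
on the cM axis: crossovers are Poisson with a configured expected count,
each switching to a uniformly drawn different founder; crossovers live on
the genetic scale because that is the recombination scale on which the 1 cM
rule is meaningful. A fraction of segments (default 1%) carries two founder
labels at half mass (residual heterozygosity), and soft probabilities mix
the truth indicator with uniform error mass (default 0.5%). Planted effects
are additive length-K founder-effect vectors, drawn centered and scaled so
the genetic variance matches a target heritability; dominance, epistasis,
linked cis pairs, count noise, and library-size artifacts are *not*
emulated, so passing tests say nothing about robustness to those features of
real data.

Scenario conditions (fixed once at design time, with power analysis, and
then frozen):

* `null` — 60 RILs, 200 markers (40 per arm, 0.5 cM spacing), 300 genes, no
  effects; used for calibration checks.
* `cis_only` — 79 RILs (a realistic panel size for this design), 200
  markers, 200 genes of which 40 carry cis effects explaining ~40% of
  variance at the marker nearest the gene.
* `hotspot_trt` — 60 RILs, 200 markers with 2 expected crossovers per
  40-marker chromosome (markers dense relative to junctions, as a 10-kb
  grid is), 300 genes of which 30 are targets of one master locus with
  treated-only trans effects at heritability 0.25 — trans effects are
  characteristically weaker than cis, and weaker effects are also what
  makes nearby shadow peaks mergeable. 300 genes keep the band-permutation
  null out of its sparse degenerate regime, where single stray hits would
  be flagged.
* `gxe` — 60 RILs, 100 markers, 320 genes with 20 planted treated-only
  effects (in-condition heritability 0.5) at gene-specific loci.
* `mixed` — a bit of everything, for end-to-end and determinism runs.

Desk-scale sizes (hundreds of markers and genes, 100–1000 permutations)
were chosen so the full suite and the acceptance script complete in minutes
while leaving every statistical property measurable; all of them scale up
through `sim_config()`.

## Numerical conventions

* All TSV writers emit UTF-8, LF endings, `NA` for missing, and numbers at
  9 significant digits; writer/reader pairs round-trip at that precision and
  repeated runs are byte-identical.
* Permutation p-values are plug-in fractions; seeds for every stochastic
  stage derive deterministically from one master seed.
* LOD values are clipped at 0 (round-off) and `Inf` flags an exact fit;
  RSS comparisons use orthonormal column bases, never explicit inverses.
* Zero-variance rows in clustering get correlation distance 1; hard founder
  calls below `min_prob = 0.8`, or exact ties, return `"ambiguous"`.

## Known limitations

* The band-permutation null ignores gene–gene correlation (anti-conservative
  under co-expression); the block-permutation flag exists precisely to gauge
  that sensitivity.
* The conditional-LOD merge cannot combine peaks separated by more than a
  few junctions at its default threshold (chance level above 1.5), so a
  weakly supported tail of a hotspot band occasionally survives as a second
  low-count region.
* Quantile normalization's two-pass operator is not exactly idempotent (see
  above).
* The G×E scan's power at realistic panel sizes is low for individual genes;
  hotspot aggregation is the intended detection route, as the analysis
  drivers illustrate.
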