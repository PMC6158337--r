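# Shared settings for the numbered analysis drivers. Every driver can be run
# from the repository root with `Rscript analysis/<script>.R`; they share one
# master seed so the whole sequence is reproducible end to end.

suppressPackageStartupMessages(library(hapeqtl))

MASTER_SEED <- 20260925L
N_PERM <- 200L            # permutations per gene / band replicate
FIXTURE_DIR <- "results/fixtures/mixed"
TABLE_DIR <- "results/tables"
FIGURE_DIR <- "results/figures"

for (d in c(TABLE_DIR, FIGURE_DIR)) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
}

load_fixture <- function() {
  if (!file.exists(file.path(FIXTURE_DIR, "expression.tsv"))) {
    stop("fixture files not found - run analysis/01_simulate.R first",
         call. = FALSE)
  }
  map <- read_marker_map(file.path(FIXTURE_DIR, "marker_map.tsv"))
  list(
    map = map,
    genotypes = read_genotype(file.path(FIXTURE_DIR, "genotype.tsv"), map),
    expression = read_expression(file.path(FIXTURE_DIR, "expression.tsv")),
    annotation = read_gene_annotation(file.path(FIXTURE_DIR, "annotation.tsv")),
    truth = read_truth_table(file.path(FIXTURE_DIR, "truth.tsv"))
  )
}

stage_seed <- function(stage) hapeqtl:::derive_seed(MASTER_SEED, stage)
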