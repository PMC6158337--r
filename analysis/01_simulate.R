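#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic panel.
#
# Writes the `mixed` scenario (60 RILs x 2 conditions, 200 markers over five
# chromosome arms, 200 genes with planted cis effects, one treated-only
# master locus, and treatment main effects) as plain TSV fixtures that the
# later drivers read back through the package's own parsers.

source("analysis/00_common.R")

paths <- make_fixture_suite("mixed", seed = MASTER_SEED, dir = FIXTURE_DIR)
tt <- read_truth_table(paths[["truth"]])

cat(sprintf("wrote %d fixture files under %s\n", length(paths), FIXTURE_DIR))
cat(sprintf("  planted cis genes:        %d\n", sum(!is.na(tt$cis_marker))))
cat(sprintf("  master-locus target genes: %d (marker %s, treated-only)\n",
            sum(!is.na(tt$trans_marker)),
            unique(na.omit(tt$trans_marker))))
cat(sprintf("  genes with |treatment effect| > 0.3: %d\n",
            sum(abs(tt$trt_effect) > 0.3)))
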