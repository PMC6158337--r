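#!/usr/bin/env Rscript
# Stage 6: reporting - the two-condition eQTL map, hierarchical clustering
# of the hotspot-associated genes, and the founder-segregation test at the
# detected master locus.

source("analysis/00_common.R")
fx <- load_fixture()
xn <- quantile_normalize_two_pass(fx$expression)

hits <- lapply(c(ctrl = "ctrl", trt = "trt"), function(cond) {
  sc <- scan_condition(xn, fx$genotypes, cond, n_perm = N_PERM,
                       seed = stage_seed(paste0("scan_", cond)))
  classify_cis_trans(significant_hits(sc), fx$annotation, fx$map)
})

map_tab <- eqtl_map_export(hits$ctrl, hits$trt, fx$map, fx$annotation,
                           path = file.path(TABLE_DIR, "eqtl_map.tsv"),
                           plot = requireNamespace("ggplot2", quietly = TRUE))
if (is.list(map_tab) && !is.null(map_tab$figure)) {
  ggplot2::ggsave(file.path(FIGURE_DIR, "eqtl_map.png"), map_tab$figure,
                  width = 7, height = 6, dpi = 150)
  map_tab <- map_tab$table
}
cat(sprintf("eQTL map: %d points (%s)\n", nrow(map_tab),
            paste(sprintf("%s=%d", names(table(map_tab$specificity)),
                          table(map_tab$specificity)), collapse = ", ")))

# cluster the master locus's associated genes on treated expression
master <- unique(na.omit(fx$truth$trans_marker))
assoc <- unique(hits$trt$gene_id[hits$trt$marker_id == master])
if (length(assoc) >= 4) {
  m <- condition_matrix(xn, "trt", fx$genotypes$ril_ids)[assoc, , drop = FALSE]
  cl <- hierarchical_cluster_order(m, "genes", k = 2)
  cat(sprintf("master-locus genes cluster into groups of %s at k = 2\n",
              paste(table(cl$groups), collapse = " and ")))
  seg <- founder_segregation_test(xn, assoc, fx$genotypes, master,
                                  condition = "trt")
  cat(sprintf("founder segregation at %s (one-way ANOVA): p = %.3g\n",
              master, seg$p))
  cat("founder group means of the gene-set expression:\n")
  print(round(seg$group_means, 3))
} else {
  cat("fewer than 4 associated genes at the master locus; skipping clustering\n")
}
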