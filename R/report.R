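#' Hierarchical clustering order of genes or samples
#'
#' Agglomerative clustering with average linkage on correlation distance
#' (`1 - Pearson r`), the transcriptomics heatmap default. Zero-variance
#' items have undefined correlation; their distance to everything is set
#' to 1. Returns the leaf order, the merge tree, and optional cut-at-k group
#' labels (e.g. the two response groups at a treated-only hotspot).
#'
#' @param values numeric matrix (genes x samples), e.g. the expression of
#'   hotspot-associated genes.
#' @param axis cluster `"genes"` (rows) or `"samples"` (columns).
#' @param k optional number of groups to cut the tree into.
#' @return list: `order` (leaf order of labels), `tree` (hclust object),
#'   `labels`, and `groups` (named integer vector when `k` given).
#' @export
hierarchical_cluster_order <- function(values, axis = c("genes", "samples"),
                                       k = NULL) {
  axis <- match.arg(axis)
  m <- if (axis == "genes") values else t(values)
  if (nrow(m) < 2) stop_input("need at least 2 items to cluster")
  sds <- apply(m, 1, stats::sd)
  cm <- suppressWarnings(stats::cor(t(m)))
  cm[!is.finite(cm)] <- 0                # zero-variance rows: distance 1
  d <- stats::as.dist(1 - cm)
  tree <- stats::hclust(d, method = "average")
  out <- list(order = rownames(m)[tree$order], tree = tree,
              labels = rownames(m))
  if (!is.null(k)) {
    out$groups <- stats::cutree(tree, k = k)
  }
  out
}

#' Founder segregation of a gene group's expression at a marker
#'
#' Formalizes the visual claim that hotspot-associated expression segregates
#' by parental origin: samples are hard-called to founders at the marker,
#' each sample is summarized by its mean expression over the gene group, and
#' a one-way test across founder groups (ANOVA by default, Kruskal-Wallis by
#' flag) is run. Ambiguous calls are excluded; founder groups with fewer
#' than `min_n` samples are dropped.
#'
#' @param x [expression_matrix].
#' @param genes character vector of gene ids (the hotspot gene group).
#' @param g [genotype_tensor].
#' @param marker_id marker at which to call founders.
#' @param condition which condition's samples to use (`"ctrl"` or `"trt"`).
#' @param test `"anova"` or `"kruskal"`.
#' @param min_n minimum samples per founder group (default 3).
#' @return list: `group_means` (mean group-expression per founder), `n`
#'   (samples per founder), `p` (one-way test p-value), `calls`.
#' @export
founder_segregation_test <- function(x, genes, g, marker_id,
                                     condition = "trt",
                                     test = c("anova", "kruskal"),
                                     min_n = 3) {
  test <- match.arg(test)
  if (!all(genes %in% rownames(x$values))) {
    stop_input("unknown gene ids in gene group")
  }
  calls <- founder_hard_call(g, marker_id)
  Ym <- condition_matrix(x, condition, g$ril_ids)   # genes x rils
  score <- colMeans(Ym[genes, , drop = FALSE])
  keep <- calls != "ambiguous"
  founder <- calls[keep]
  score <- score[keep]
  tab <- table(founder)
  ok <- names(tab)[tab >= min_n]
  if (length(ok) < 2) {
    stop_input("fewer than 2 founder groups with >= %d samples at %s",
               min_n, marker_id)
  }
  sel <- founder %in% ok
  founder <- factor(founder[sel])
  score <- score[sel]
  p <- if (test == "anova") {
    summary(stats::aov(score ~ founder))[[1]][["Pr(>F)"]][1]
  } else {
    stats::kruskal.test(score, founder)$p.value
  }
  list(group_means = tapply(score, founder, mean),
       n = table(founder), p = p, calls = calls)
}

#' Plot-ready eQTL map of both condition scans
#'
#' One row per significant (gene, marker) association: x is the marker's
#' offset on the concatenated genome, y the gene midpoint's offset, and the
#' color class marks shared / ctrl-only / trt-only signals — the classic
#' eQTL map whose diagonal is the cis band and whose vertical bands are
#' trans hotspots.
#'
#' @param hits_ctrl,hits_trt classified hit tables ([classify_cis_trans]).
#' @param map [marker_map].
#' @param ann [gene_annotation].
#' @param path optional TSV output path.
#' @param plot if TRUE also return a ggplot scatter (requires ggplot2).
#' @return data.frame (`gene_id`, `marker_id`, `marker_offset_bp`,
#'   `gene_offset_bp`, `class`, `specificity`); with `plot = TRUE`, a list
#'   `(table, figure)`.
#' @export
eqtl_map_export <- function(hits_ctrl, hits_trt, map, ann, path = NULL,
                            plot = FALSE) {
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(ch) max(map$pos_bp[map$chrom == ch]), 0)
  offset <- stats::setNames(cumsum(c(0, chrom_len[-length(chrom_len)])), chroms)
  both <- rbind(hits_ctrl, hits_trt)
  if (nrow(both)) {
    key <- paste(both$gene_id, both$marker_id)
    in_c <- key %in% paste(hits_ctrl$gene_id, hits_ctrl$marker_id)
    in_t <- key %in% paste(hits_trt$gene_id, hits_trt$marker_id)
    spec <- ifelse(in_c & in_t, "shared", ifelse(in_c, "ctrl-only", "trt-only"))
    mi <- match(both$marker_id, map$marker_id)
    gi <- match(both$gene_id, ann$gene_id)
    tab <- data.frame(
      gene_id = both$gene_id, marker_id = both$marker_id,
      marker_offset_bp = offset[map$chrom[mi]] + map$pos_bp[mi],
      gene_offset_bp = offset[ann$chrom[gi]] +
        (ann$start_bp[gi] + ann$end_bp[gi]) / 2,
      class = both$class, specificity = spec, stringsAsFactors = FALSE
    )
    tab <- unique(tab)
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(gene_id = character(0), marker_id = character(0),
                      marker_offset_bp = numeric(0),
                      gene_offset_bp = numeric(0), class = character(0),
                      specificity = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(path)) write_tsv_exact(tab, path)
  if (plot) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      stop_input("plot = TRUE requires ggplot2")
    }
    tab_mb <- transform(tab, marker_mb = marker_offset_bp / 1e6,
                        gene_mb = gene_offset_bp / 1e6)
    fig <- ggplot2::ggplot(tab_mb, ggplot2::aes(
      x = marker_mb, y = gene_mb, colour = specificity)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::scale_colour_manual(values = c(
        shared = "brown", `ctrl-only` = "darkgreen", `trt-only` = "red"),
        drop = FALSE) +
      ggplot2::labs(x = "eQTL location (Mb, concatenated genome)",
                    y = "transcript location (Mb)", colour = NULL) +
      ggplot2::theme_minimal()
    return(list(table = tab, figure = fig))
  }
  tab
}
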