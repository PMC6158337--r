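# Naive average-linkage agglomeration on 1 - cor distance, independent of
# stats::hclust, used as the clustering oracle on small instances.
naive_average_cut <- function(m, k) {
  n <- nrow(m)
  d <- 1 - cor(t(m))
  diag(d) <- NA
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (b <= a) next
      dist_ab <- mean(d[groups[[a]], groups[[b]]])
      if (dist_ab < bestd) { bestd <- dist_ab; best <- c(a, b) }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(groups)) lab[groups[[i]]] <- i
  lab
}

test_that("identical genes merge first and sit on adjacent leaves", {
  set.seed(60)
  m <- matrix(rnorm(6 * 10), 6, 10, dimnames = list(paste0("g", 1:6), NULL))
  m[4, ] <- m[2, ]
  cl <- hierarchical_cluster_order(m, "genes")
  pos <- match(c("g2", "g4"), cl$order)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(cl$tree$height[1], 0, tolerance = 1e-12)
})

test_that("cluster partitions match a naive agglomerative oracle", {
  set.seed(61)
  for (rep in 1:10) {
    m <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(paste0("g", 1:8), NULL))
    k <- sample(2:4, 1)
    cl <- hierarchical_cluster_order(m, "genes", k = k)
    ref <- naive_average_cut(m, k)
    # same partition up to label renaming
    tab <- table(cl$groups, ref)
    expect_equal(sum(tab > 0), k)
  }
})

test_that("zero-variance rows cluster without error at distance 1", {
  m <- rbind(g1 = rep(2, 8), g2 = rnorm(8), g3 = rnorm(8))
  expect_no_error(cl <- hierarchical_cluster_order(m, "genes"))
  expect_setequal(cl$order, rownames(m))
})

test_that("cutting at k = 2 separates up- from down-responding hotspot genes", {
  set.seed(62)
  cfg <- sim_config(n_rils = 60, markers_per_chrom = 6, sigma = 0.4, seed = 70)
  g <- simulate_ril_genotypes(cfg)$genotypes
  master <- g$map$marker_id[3]
  base <- hapeqtl:::draw_founder_effects(8, 0.5)
  eff <- c(replicate(10, base + rnorm(8, 0, 0.1), simplify = FALSE),
           replicate(10, -base + rnorm(8, 0, 0.1), simplify = FALSE))
  tt <- truth_table(sprintf("G%02d", 1:20), trans_marker = master,
                    trans_effects = eff, trans_scope = "trt-only")
  ex <- simulate_expression_pair(g, tt, cfg)
  m <- condition_matrix(ex$expression, "trt", g$ril_ids)
  cl <- hierarchical_cluster_order(m, "genes", k = 2)
  truth_side <- rep(1:2, each = 10)
  tab <- table(cl$groups, truth_side)
  agreement <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / 20
  expect_gte(agreement, 0.9)
})

test_that("founder segregation is detected at a planted master locus", {
  set.seed(63)
  detected <- vapply(1:5, function(i) {
    cfg <- sim_config(n_rils = 70, markers_per_chrom = 6, sigma = 0.4,
                      seed = 80 + i)
    g <- simulate_ril_genotypes(cfg)$genotypes
    master <- g$map$marker_id[3]
    eff <- replicate(8, hapeqtl:::draw_founder_effects(8, 0.4), simplify = FALSE)
    tt <- truth_table(sprintf("G%02d", 1:8), trans_marker = master,
                      trans_effects = eff, trans_scope = "both")
    ex <- simulate_expression_pair(g, tt, cfg)
    res <- founder_segregation_test(ex$expression, sprintf("G%02d", 1:8),
                                    g, master, condition = "trt")
    res$p
  }, 0)
  expect_gte(mean(detected < 0.01), 0.8)
  # mean group-expression with no planted effect: no systematic segregation
  cfg <- sim_config(n_rils = 70, markers_per_chrom = 6, seed = 90)
  g <- simulate_ril_genotypes(cfg)$genotypes
  tt <- truth_table(sprintf("G%02d", 1:8))
  ex <- simulate_expression_pair(g, tt, cfg)
  res <- founder_segregation_test(ex$expression, sprintf("G%02d", 1:8),
                                  g, g$map$marker_id[3], condition = "trt",
                                  test = "kruskal")
  expect_true(res$p >= 0 && res$p <= 1)
})

test_that("the eQTL map geometry reflects the planted architecture", {
  # empty hit set -> empty table
  sim <- cached_scenario("cis_only")
  empty <- data.frame(gene_id = character(0), marker_id = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  tab0 <- eqtl_map_export(empty, empty, sim$map, sim$annotation)
  expect_equal(nrow(tab0), 0)

  # cis-only: points concentrate on the diagonal
  sc <- cached_scan("cis_only", "ctrl")
  hits <- classify_cis_trans(significant_hits(sc), sim$annotation, sim$map)
  tab <- eqtl_map_export(hits, empty, sim$map, sim$annotation)
  cis_frac <- mean(abs(tab$marker_offset_bp - tab$gene_offset_bp) < 30000)
  expect_gt(cis_frac, 0.5)

  # treated-only hotspot: a vertical band at the master marker in trt only
  simh <- cached_scenario("hotspot_trt")
  master <- unique(na.omit(simh$truth$trans_marker))
  sct <- cached_scan("hotspot_trt", "trt")
  scc <- cached_scan("hotspot_trt", "ctrl")
  ht <- classify_cis_trans(significant_hits(sct), simh$annotation, simh$map)
  hc <- classify_cis_trans(significant_hits(scc), simh$annotation, simh$map)
  tabh <- eqtl_map_export(hc, ht, simh$map, simh$annotation)
  at_master <- tabh[tabh$marker_id == master, ]
  expect_gte(sum(at_master$specificity == "trt-only"), 10)
  expect_equal(sum(at_master$specificity == "ctrl-only"), 0)

  # report export is a pure function of its inputs
  expect_identical(tabh, eqtl_map_export(hc, ht, simh$map, simh$annotation))
})

test_that("the full pipeline is deterministic and honors stage skipping", {
  cfgbase <- list(scenario = "mixed", seed = 11L, n_perm = 100L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- run_pipeline(c(cfgbase, list(out = d1)))
  p2 <- run_pipeline(c(cfgbase, list(out = d2)))
  expect_setequal(names(p1), names(p2))
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     info = nm)
  }
  d3 <- withr::local_tempdir()
  p3 <- run_pipeline(c(cfgbase, list(out = d3, skip = "gxe")))
  expect_false("gxe_top" %in% names(p3))
  common <- intersect(names(p1), names(p3))
  for (nm in common) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p3[[nm]])),
                     info = nm)
  }
})

test_that("pipeline configs parse from key=value files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("scenario = gxe", "n_perm = 150  # fast", "skip = gxe,report",
               "alpha = 0.1"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$scenario, "gxe")
  expect_equal(cfg$n_perm, 150L)
  expect_equal(cfg$skip, c("gxe", "report"))
  expect_equal(cfg$alpha, 0.1)
  writeLines("bogus = 1", path)
  expect_error(read_pipeline_config(path), "unknown config key")
})
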