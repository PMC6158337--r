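test_that("zero expected crossovers give single-founder chromosomes", {
  cfg <- sim_config(n_rils = 12, markers_per_chrom = 10,
                    crossovers_per_chrom = 0, het_rate = 0, seed = 4)
  sim <- simulate_ril_genotypes(cfg)
  tr <- sim$truth$primary
  for (ch in cfg$chroms) {
    idx <- sim$genotypes$map$chrom == ch
    expect_true(all(apply(tr[, idx, drop = FALSE], 1,
                          function(v) length(unique(v)) == 1)))
  }
})

test_that("no heterozygosity and no error give one-hot probabilities", {
  cfg <- sim_config(n_rils = 8, markers_per_chrom = 10, het_rate = 0,
                    geno_error = 0, seed = 2)
  sim <- simulate_ril_genotypes(cfg)
  p <- sim$genotypes$prob
  expect_true(all(p %in% c(0, 1)))
  expect_true(all(apply(p, c(1, 2), sum) == 1))
})

test_that("founder labels form runs matching the junction process", {
  cfg <- sim_config(n_rils = 200, markers_per_chrom = 40,
                    crossovers_per_chrom = 2, het_rate = 0, seed = 6)
  sim <- simulate_ril_genotypes(cfg)
  tr <- sim$truth$primary
  runs <- 0
  for (ch in cfg$chroms) {
    idx <- sim$genotypes$map$chrom == ch
    runs <- runs + sum(apply(tr[, idx], 1, function(v) length(rle(v)$lengths)))
  }
  mean_runs <- runs / (cfg$n_rils * length(cfg$chroms))
  # slightly below 1 + E[crossovers]: junctions can fall outside the marker
  # span or share an inter-marker gap
  expect_lt(abs(mean_runs - 3), 0.25)
})

test_that("genome-wide founder frequencies are uniform at large panel size", {
  cfg <- sim_config(n_rils = 200, markers_per_chrom = 40, seed = 8)
  sim <- simulate_ril_genotypes(cfg)
  tr <- sim$truth$primary
  K <- length(cfg$founders)
  freq <- table(factor(tr, levels = cfg$founders)) / length(tr)
  n_seg <- sum(sim$truth$n_segments)
  # variable segment lengths roughly double the binomial variance
  se <- sqrt(2 * (1 / K) * (1 - 1 / K) / n_seg)
  expect_true(all(abs(freq - 1 / K) <= 3 * se))
})

test_that("heterozygous-marker fraction tracks the configured rate", {
  cfg <- sim_config(n_rils = 100, markers_per_chrom = 40, het_rate = 0.01, seed = 9)
  sim <- simulate_ril_genotypes(cfg)
  frac <- mean(!is.na(sim$truth$secondary))
  expect_gte(frac, 0.5 * cfg$het_rate)
  expect_lte(frac, 2 * cfg$het_rate)
})

test_that("expression with no effects is pure noise around the grand mean", {
  cfg <- sim_config(n_rils = 100, markers_per_chrom = 5, n_genes = 50,
                    mu = 5, sigma = 0.5, seed = 10)
  g <- simulate_ril_genotypes(cfg)$genotypes
  tt <- truth_table(sprintf("G%02d", 1:50))
  ex <- simulate_expression_pair(g, tt, cfg)
  v <- ex$expression$values
  expect_equal(mean(v), 5, tolerance = 0.02)
  expect_equal(sd(as.vector(v)), 0.5, tolerance = 0.05)
})

test_that("a planted treatment effect shows up as the paired mean difference", {
  cfg <- sim_config(n_rils = 150, markers_per_chrom = 5, n_genes = 40,
                    sigma = 0.5, seed = 11)
  g <- simulate_ril_genotypes(cfg)$genotypes
  tt <- truth_table(sprintf("G%02d", 1:40), trt_effect = 1.0)
  ex <- simulate_expression_pair(g, tt, cfg)
  yc <- condition_matrix(ex$expression, "ctrl")
  yt <- condition_matrix(ex$expression, "trt")
  expect_equal(mean(yt - yc), 1.0, tolerance = 0.03)
})

test_that("treated-only trans effects couple genotype and expression only after treatment", {
  cfg <- sim_config(n_rils = 120, markers_per_chrom = 5, n_genes = 30,
                    sigma = 0.5, seed = 12)
  g <- simulate_ril_genotypes(cfg)$genotypes
  master <- g$map$marker_id[3]
  eff <- lapply(1:30, function(i) {
    set.seed(100 + i); hapeqtl:::draw_founder_effects(8, 0.25)
  })
  tt <- truth_table(sprintf("G%02d", 1:30), trans_marker = master,
                    trans_effects = eff, trans_scope = "trt-only")
  ex <- simulate_expression_pair(g, tt, cfg)
  P <- hapeqtl:::marker_probs(g, master)
  r2 <- function(m) {
    mean(vapply(seq_len(nrow(m)), function(j) {
      summary(lm(m[j, ] ~ P))$r.squared
    }, 0))
  }
  r2_trt <- r2(condition_matrix(ex$expression, "trt", g$ril_ids))
  r2_ctrl <- r2(condition_matrix(ex$expression, "ctrl", g$ril_ids))
  expect_gt(r2_trt, r2_ctrl + 0.1)
})

test_that("fixture suites are deterministic and record the planted architecture", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture_suite("hotspot_trt", seed = 21, dir = d1)
  p2 <- make_fixture_suite("hotspot_trt", seed = 21, dir = d2)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])), unname(tools::md5sum(p2[[nm]])),
                     info = nm)
  }
  tt <- read_truth_table(p1[["truth"]])
  masters <- unique(stats::na.omit(tt$trans_marker))
  expect_length(masters, 1)
  expect_gte(sum(!is.na(tt$trans_marker)), 30)

  tt_null <- read_truth_table(make_fixture_suite("null", 5, withr::local_tempdir())[["truth"]])
  expect_true(all(is.na(tt_null$cis_marker)))
  expect_true(all(is.na(tt_null$trans_marker)))
  expect_true(all(tt_null$trt_effect == 0))

  expect_error(make_fixture_suite("bogus", 1, withr::local_tempdir()), "scenario")
})

test_that("truth tables round-trip through TSV including effect vectors", {
  set.seed(14)
  tt <- truth_table(c("g1", "g2", "g3"),
                    cis_marker = c("m1", NA, NA),
                    cis_effects = list(rnorm(8), NULL, NULL),
                    trans_marker = c(NA, "m5", NA),
                    trans_effects = list(NULL, rnorm(8), NULL),
                    trans_scope = c(NA, "trt-only", NA),
                    trt_effect = c(0, 0.5, 0), interaction = c(FALSE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(tt, path)
  tt2 <- read_truth_table(path)
  expect_equal(tt2$cis_effects[[1]], tt$cis_effects[[1]], tolerance = 1e-8)
  expect_equal(tt2$trans_effects[[2]], tt$trans_effects[[2]], tolerance = 1e-8)
  expect_identical(tt2$trans_scope, tt$trans_scope)
  expect_identical(tt2$interaction, tt$interaction)
})
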