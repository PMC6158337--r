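# Brute-force oracle: explicit normal equations with pseudo-inversion.
fit_oracle_rss <- function(y, G) {
  X <- cbind(1, G)
  beta <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
  sum((y - X %*% beta)^2)
}

# Explicitly maximized Gaussian likelihoods for the LOD identity.
loglik_hat <- function(y, fitted) {
  s2 <- mean((y - fitted)^2)
  sum(dnorm(y, fitted, sqrt(s2), log = TRUE))
}

test_that("founder regression RSS matches an explicit pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  set.seed(20)
  for (i in 1:50) {
    n <- sample(15:40, 1); K <- sample(c(2, 4, 8), 1)
    G <- random_probs(n, K)
    y <- rnorm(n) + G %*% rnorm(K)
    fit <- fit_founder_regression(y, G)
    expect_equal(fit$rss, fit_oracle_rss(y, G), tolerance = 1e-8)
  }
})

test_that("degenerate designs collapse cleanly", {
  set.seed(21)
  y <- rnorm(12)
  # identical founder rows carry no genetic information
  G_same <- matrix(rep(c(0.5, 0.5, 0, 0), each = 12), 12, 4)
  f0 <- fit_founder_regression(y)
  f1 <- fit_founder_regression(y, G_same)
  expect_equal(f1$rss, f0$rss, tolerance = 1e-9)
  expect_equal(lod_from_fits(f0, f1), 0)

  # one-hot groups with constant values within groups fit perfectly
  G <- diag(4)[rep(1:4, each = 3), ]
  yg <- rep(c(1, 2, 3, 4), each = 3)
  expect_lt(fit_founder_regression(yg, G)$rss, 1e-18)
  expect_error(fit_founder_regression(1), "at least 2")
})

test_that("the LOD equals the log10 ratio of maximized Gaussian likelihoods", {
  set.seed(22)
  for (i in 1:20) {
    n <- 25; K <- 8
    G <- random_probs(n, K)
    y <- rnorm(n) + G %*% rnorm(K, sd = 0.8)
    f0 <- fit_founder_regression(y)
    f1 <- fit_founder_regression(y, G)
    lod <- lod_from_fits(f0, f1)
    X <- cbind(1, G)
    beta <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
    ref <- (loglik_hat(y, X %*% beta) - loglik_hat(y, rep(mean(y), n))) / log(10)
    expect_equal(lod, ref, tolerance = 1e-8)
    expect_gt(lod, 0)   # RSS1 < RSS0 here
  }
  expect_equal(hapeqtl:::lod_from_rss(0, 0, 30), 0)
  expect_identical(hapeqtl:::lod_from_rss(2, 0, 30), Inf)
})

test_that("scan results are invariant to how the rank deficiency is resolved", {
  sim <- cached_scenario("cis_only")
  g <- sim$genotypes
  y <- condition_matrix(sim$expression, "ctrl", g$ril_ids)[1, ]
  prof <- scan_gene(y, g)
  # reduced parameterization: drop the last founder column entirely
  for (mk in g$map$marker_id[seq(1, 200, by = 23)]) {
    P <- hapeqtl:::marker_probs(g, mk)
    fit_red <- lm.fit(cbind(1, P[, -ncol(P)]), y)
    rss_red <- sum(fit_red$residuals^2)
    f0 <- fit_founder_regression(y)
    lod_red <- hapeqtl:::lod_from_rss(f0$rss, rss_red, length(y))
    expect_equal(prof$lod[prof$marker_id == mk], lod_red, tolerance = 1e-9)
  }
})

test_that("a planted linear signal peaks at the planted marker", {
  set.seed(23)
  cfg <- sim_config(n_rils = 60, markers_per_chrom = 20, seed = 30)
  g <- simulate_ril_genotypes(cfg)$genotypes
  for (i in 1:5) {
    mk <- sample(g$map$marker_id, 1)
    beta <- hapeqtl:::draw_founder_effects(8, 1)
    y <- drop(hapeqtl:::marker_probs(g, mk) %*% beta)   # noiseless
    prof <- scan_gene(y, g)
    peak <- prof$marker_id[which.max(prof$lod)]
    # the peak is the planted marker or one in (near-)perfect linkage with it
    r <- cor(drop(hapeqtl:::marker_probs(g, peak) %*% beta), y)
    expect_gte(r, 1 - 1e-6)
  }
  expect_equal(nrow(scan_gene(rnorm(60), g)), nrow(g$map))
  expect_error(scan_gene(rnorm(10), g), "length")
})

test_that("adding the planted signal never lowers the LOD at the planted marker", {
  set.seed(24)
  cfg <- sim_config(n_rils = 40, markers_per_chrom = 8, seed = 31)
  g <- simulate_ril_genotypes(cfg)$genotypes
  eng <- hapeqtl:::scan_engine(g)
  delta <- vapply(1:50, function(i) {
    mk_i <- sample(nrow(g$map), 1)
    beta <- hapeqtl:::draw_founder_effects(8, 0.5)
    y0 <- rnorm(40)
    sig <- drop(matrix(g$prob[, mk_i, ], 40) %*% beta)
    l0 <- hapeqtl:::lod_matrix(eng, cbind(y0))[mk_i, 1]
    l1 <- hapeqtl:::lod_matrix(eng, cbind(y0 + sig))[mk_i, 1]
    l1 - l0
  }, 0)
  # noise anti-correlated with the planted contrast can cancel part of the
  # signal in individual draws; the gain must dominate across draws
  expect_gte(mean(delta >= -1e-9), 0.85)
  expect_gt(mean(delta), 0)
})

test_that("permutation p-values hit their logical extremes and reproduce", {
  cfg <- sim_config(n_rils = 30, markers_per_chrom = 6, seed = 32)
  g <- simulate_ril_genotypes(cfg)$genotypes
  # perfect genetic fit: observed LOD above every permutation maximum
  beta <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- drop(hapeqtl:::marker_probs(g, g$map$marker_id[3]) %*% beta)
  pp <- permutation_pvalues(y, g, n_perm = 100, seed = 1)
  expect_equal(min(pp$p), 0)
  # constant response: observed LOD 0 at or below every maximum
  pc <- permutation_pvalues(rep(1, 30), g, n_perm = 100, seed = 1)
  expect_true(all(pc$p == 1))
  # smoothing bounds p away from zero
  ps <- permutation_pvalues(y, g, n_perm = 100, seed = 1, smooth = TRUE)
  expect_equal(min(ps$p), 1 / 101)
  # determinism
  p1 <- permutation_pvalues(y + rnorm(30), g, n_perm = 100, seed = 7)
  expect_error(permutation_pvalues(y, g, n_perm = 50), "at least 100")
  sim_y <- y + rnorm(30)
  expect_identical(permutation_pvalues(sim_y, g, n_perm = 100, seed = 9)$p,
                   permutation_pvalues(sim_y, g, n_perm = 100, seed = 9)$p)
})

test_that("condition scans reproduce under a fixed seed", {
  sim <- cached_scenario("cis_only")
  xn <- cached_normalized("cis_only")
  s1 <- scan_condition(xn, sim$genotypes, "ctrl", n_perm = 100, seed = 99)
  s2 <- scan_condition(xn, sim$genotypes, "ctrl", n_perm = 100, seed = 99)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$lod, s2$lod)
})

test_that("Storey q-values match an independently coded estimator", {
  # independent oracle: explicit min-over-larger-p search
  oracle_q <- function(p) {
    m <- length(p)
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- sapply(lambda, function(l) mean(p > l) / (1 - l))
    pi0 <- predict(smooth.spline(lambda, pi0_l, df = 3), x = 0.95)$y
    if (pi0 > 1) pi0 <- 1
    if (m < 100) pi0 <- 1
    vapply(p, function(pi) {
      larger <- p[p >= pi]
      min(vapply(larger, function(pj) pi0 * m * pj / sum(p <= pj), 0), 1)
    }, 0)
  }
  set.seed(25)
  p <- c(runif(700)^2, runif(300))   # enrichment near zero
  expect_equal(storey_qvalue(p), oracle_q(p), tolerance = 1e-6)
  expect_equal(storey_qvalue(rep(1, 20)), rep(1, 20))
  expect_error(storey_qvalue(c(0.5, 1.2)), "\\[0,1\\]")
  # q is monotone non-decreasing in p
  o <- order(p)
  expect_true(all(diff(storey_qvalue(p)[o]) >= -1e-12))
})

test_that("cis/trans classification applies the inclusive 1 cM rule", {
  map <- marker_map(data.frame(
    marker_id = c("m1", "m2", "m3"), chrom = c("2L", "2L", "3R"),
    pos_bp = c(10000L, 20000L, 10000L), cM = c(1, 2, 1)))
  ann <- gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = c("2L", "2L", "2L"),
    start_bp = c(9500L, 29500L, 9500L), end_bp = c(10499L, 30499L, 10499L),
    strand = "."))
  hits <- data.frame(
    gene_id = c("gA", "gB", "gA", "gZ"),
    marker_id = c("m1", "m1", "m3", "m1"),
    stringsAsFactors = FALSE)
  expect_warning(out <- classify_cis_trans(hits, ann, map), "unannotated")
  # overlapping peak -> cis; cross-chromosome -> trans
  expect_equal(out$class[out$gene_id == "gA" & out$marker_id == "m1"], "cis")
  expect_equal(out$class[out$gene_id == "gA" & out$marker_id == "m3"], "trans")
  # gB midpoint interpolates beyond the last marker: clamped to 2 cM,
  # exactly 1.0 cM from m1 -> cis (boundary is inclusive)
  expect_equal(out$distance_cM[out$gene_id == "gB"], 1.0)
  expect_equal(out$class[out$gene_id == "gB"], "cis")
})

test_that("condition specificity partitions gene-level classes", {
  hc <- data.frame(gene_id = c("g1", "g2"), class = c("cis", "trans"),
                   stringsAsFactors = FALSE)
  ht <- data.frame(gene_id = c("g1", "g3"), class = c("cis", "trans"),
                   stringsAsFactors = FALSE)
  sp <- condition_specificity(hc, ht)
  expect_equal(sp$specificity[sp$gene_id == "g1"], "shared")
  expect_equal(sp$specificity[sp$gene_id == "g2"], "ctrl-specific")
  expect_equal(sp$specificity[sp$gene_id == "g3"], "trt-specific")
  empty <- hc[0, ]
  sp2 <- condition_specificity(hc, empty)
  expect_true(all(sp2$specificity == "ctrl-specific"))
})
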