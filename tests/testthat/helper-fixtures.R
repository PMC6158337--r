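# Shared simulated fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_scenario <- function(scenario, seed = 1L) {
  key <- paste0("sim_", scenario, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_scenario(scenario, seed)
  }
  .fixture_cache[[key]]
}

cached_scan <- function(scenario, condition, seed = 1L, n_perm = 200) {
  key <- paste0("scan_", scenario, "_", condition, "_", seed, "_", n_perm)
  if (is.null(.fixture_cache[[key]])) {
    sim <- cached_scenario(scenario, seed)
    xn <- cached_normalized(scenario, seed)
    .fixture_cache[[key]] <- scan_condition(
      xn, sim$genotypes, condition, n_perm = n_perm,
      seed = hapeqtl:::derive_seed(seed, paste0("scan_", condition)))
  }
  .fixture_cache[[key]]
}

cached_normalized <- function(scenario, seed = 1L) {
  key <- paste0("norm_", scenario, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      quantile_normalize_two_pass(cached_scenario(scenario, seed)$expression)
  }
  .fixture_cache[[key]]
}

# Tiny hand-built genotype tensor: n RILs, markers on one or two chromosomes,
# hard founder assignments given as a label matrix.
toy_tensor <- function(labels, founders = paste0("A", 1:4),
                       chrom = rep("2L", ncol(labels)), cM_step = 1) {
  n_r <- nrow(labels); n_m <- ncol(labels)
  map <- marker_map(data.frame(
    marker_id = paste0("m", seq_len(n_m)), chrom = chrom,
    pos_bp = rep(seq_len(n_m), length.out = n_m) * 10000L,
    cM = ave(seq_len(n_m), chrom, FUN = seq_along) * cM_step))
  prob <- array(0, dim = c(n_r, n_m, length(founders)),
                dimnames = list(paste0("R", seq_len(n_r)), map$marker_id, founders))
  for (i in seq_len(n_r)) for (j in seq_len(n_m)) {
    prob[i, j, match(labels[i, j], founders)] <- 1
  }
  genotype_tensor(prob, map)
}

random_probs <- function(n, K) {
  p <- matrix(stats::rexp(n * K), n, K)
  p / rowSums(p)
}
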