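#' Simulation configuration for founder-mosaic RIL panels
#'
#' Defaults describe a desk-scale panel that mirrors the structure of an
#' eight-founder recombinant inbred line resource: homozygous mosaics of
#' eight founders over a junction-marker grid, ~1% residual heterozygosity,
#' 0.5% genotyping error in the soft founder probabilities, and paired
#' control/treated expression per RIL.
#'
#' @param n_rils number of RILs (>= 4).
#' @param founders founder labels (2..16 of them).
#' @param chroms chromosome names.
#' @param markers_per_chrom junction markers per chromosome.
#' @param segment_bp physical spacing between junction markers.
#' @param cM_per_marker genetic spacing between adjacent markers.
#' @param crossovers_per_chrom expected crossover count per chromosome per RIL.
#' @param het_rate residual heterozygosity rate per mosaic segment.
#' @param geno_error genotyping error rate mixed into soft probabilities.
#' @param n_genes number of genes to simulate.
#' @param mu grand mean expression (log2 scale).
#' @param sigma residual noise standard deviation.
#' @param seed master seed; all stage streams derive from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_rils = 60, founders = paste0("A", 1:8),
                       chroms = c("X", "2L", "2R", "3L", "3R"),
                       markers_per_chrom = 60, segment_bp = 10000L,
                       cM_per_marker = 0.5, crossovers_per_chrom = 3,
                       het_rate = 0.01, geno_error = 0.005,
                       n_genes = 500, mu = 5, sigma = 0.5, seed = 1L) {
  cfg <- list(n_rils = n_rils, founders = founders, chroms = chroms,
              markers_per_chrom = markers_per_chrom, segment_bp = segment_bp,
              cM_per_marker = cM_per_marker,
              crossovers_per_chrom = crossovers_per_chrom,
              het_rate = het_rate, geno_error = geno_error,
              n_genes = n_genes, mu = mu, sigma = sigma, seed = as.integer(seed))
  stopifnot(cfg$n_rils >= 4, length(cfg$founders) >= 2,
            cfg$het_rate >= 0, cfg$het_rate <= 1,
            cfg$geno_error >= 0, cfg$geno_error <= 1, cfg$sigma > 0)
  class(cfg) <- "sim_config"
  cfg
}

sim_map <- function(cfg) {
  rows <- lapply(cfg$chroms, function(ch) {
    i <- seq_len(cfg$markers_per_chrom)
    data.frame(marker_id = sprintf("%s_%d", ch, cfg$segment_bp * i),
               chrom = ch, pos_bp = cfg$segment_bp * i,
               cM = cfg$cM_per_marker * i, stringsAsFactors = FALSE)
  })
  marker_map(do.call(rbind, rows))
}

#' Simulate founder-mosaic RIL genotypes
#'
#' Each RIL chromosome is a junction process on the genetic (cM) axis: the
#' founder at the left end is drawn uniformly, crossover points follow a
#' memoryless (Poisson) process with the configured expected count, and each
#' crossover switches to a uniformly drawn different founder. A fraction
#' `het_rate` of mosaic segments carries two founder labels at half mass
#' (residual heterozygosity). Soft probabilities mix the truth indicator with
#' uniform error mass at rate `geno_error`.
#'
#' @param cfg [sim_config].
#' @return list: `genotypes` ([genotype_tensor]), `truth` with `primary` and
#'   `secondary` founder-label matrices (RIL x marker; `secondary` is NA for
#'   homozygous markers) and `n_segments` (RIL x chromosome junction counts).
#' @export
simulate_ril_genotypes <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "genotypes"))
  map <- sim_map(cfg)
  K <- length(cfg$founders)
  n_m <- nrow(map)
  rils <- sprintf("RIL%03d", seq_len(cfg$n_rils))
  primary <- matrix(NA_character_, cfg$n_rils, n_m, dimnames = list(rils, map$marker_id))
  secondary <- matrix(NA_character_, cfg$n_rils, n_m, dimnames = list(rils, map$marker_id))
  n_segments <- matrix(0L, cfg$n_rils, length(cfg$chroms),
                       dimnames = list(rils, cfg$chroms))
  for (r in seq_len(cfg$n_rils)) {
    for (ci in seq_along(cfg$chroms)) {
      ch <- cfg$chroms[ci]
      idx <- which(map$chrom == ch)
      cm <- map$cM[idx]
      chrom_len <- max(cm) + cfg$cM_per_marker
      n_x <- stats::rpois(1, cfg$crossovers_per_chrom)
      brk <- sort(stats::runif(n_x, 0, chrom_len))
      seg_of_marker <- findInterval(cm, brk) + 1L
      n_seg <- n_x + 1L
      lab <- character(n_seg)
      lab[1] <- sample(cfg$founders, 1)
      if (n_seg > 1) {
        for (s in 2:n_seg) lab[s] <- sample(setdiff(cfg$founders, lab[s - 1]), 1)
      }
      het <- stats::runif(n_seg) < cfg$het_rate
      lab2 <- rep(NA_character_, n_seg)
      if (any(het)) {
        lab2[het] <- vapply(lab[het],
                            function(f) sample(setdiff(cfg$founders, f), 1), "")
      }
      primary[r, idx] <- lab[seg_of_marker]
      secondary[r, idx] <- lab2[seg_of_marker]
      n_segments[r, ci] <- n_seg
    }
  }
  prob <- array(0, dim = c(cfg$n_rils, n_m, K),
                dimnames = list(rils, map$marker_id, cfg$founders))
  pk <- match(primary, cfg$founders)
  sk <- match(secondary, cfg$founders)
  rm_idx <- cbind(rep(seq_len(cfg$n_rils), n_m), rep(seq_len(n_m), each = cfg$n_rils))
  hom <- is.na(as.vector(sk))
  prob[cbind(rm_idx[hom, , drop = FALSE], as.vector(pk)[hom])] <- 1
  if (any(!hom)) {
    prob[cbind(rm_idx[!hom, , drop = FALSE], as.vector(pk)[!hom])] <- 0.5
    prob[cbind(rm_idx[!hom, , drop = FALSE], as.vector(sk)[!hom])] <- 0.5
  }
  prob <- (1 - cfg$geno_error) * prob + cfg$geno_error / K
  list(genotypes = genotype_tensor(prob, map),
       truth = list(primary = primary, secondary = secondary,
                    n_segments = n_segments))
}

# Per-founder effect vector with zero mean and population variance var_target
# over the K founders (the variance an additive one-hot genotype contributes).
draw_founder_effects <- function(K, var_target) {
  b <- stats::rnorm(K)
  b <- b - mean(b)
  b * sqrt(var_target / mean(b^2))
}

empty_truth <- function(gene_ids) {
  data.frame(gene_id = gene_ids,
             cis_marker = NA_character_,
             trans_marker = NA_character_,
             trans_scope = NA_character_,
             trt_effect = 0,
             interaction = FALSE,
             stringsAsFactors = FALSE)
}

#' Construct a truth table of planted effects
#'
#' @param gene_ids gene identifiers.
#' @param cis_marker,trans_marker per-gene marker ids or NA.
#' @param cis_effects,trans_effects lists of length-K founder effect vectors
#'   (NULL entries for genes without the effect).
#' @param trans_scope per-gene condition scope: `both`, `ctrl-only`,
#'   `trt-only`, or NA.
#' @param trt_effect per-gene treatment main effect (log2 units).
#' @param interaction logical flag marking planted genotype-by-environment genes.
#' @return a `truth_table` data.frame with list columns for effect vectors.
#' @export
truth_table <- function(gene_ids, cis_marker = NA, cis_effects = NULL,
                        trans_marker = NA, trans_effects = NULL,
                        trans_scope = NA, trt_effect = 0, interaction = FALSE) {
  n <- length(gene_ids)
  tt <- empty_truth(gene_ids)
  tt$cis_marker <- rep_len(as.character(cis_marker), n)
  tt$trans_marker <- rep_len(as.character(trans_marker), n)
  tt$trans_scope <- rep_len(as.character(trans_scope), n)
  tt$trt_effect <- rep_len(as.numeric(trt_effect), n)
  tt$interaction <- rep_len(as.logical(interaction), n)
  tt$cis_effects <- cis_effects %||% rep(list(NULL), n)
  tt$trans_effects <- trans_effects %||% rep(list(NULL), n)
  ok <- is.na(tt$trans_scope) | tt$trans_scope %in% c("both", "ctrl-only", "trt-only")
  if (!all(ok)) stop_input("invalid trans_scope value")
  class(tt) <- c("truth_table", "data.frame")
  tt
}

#' Simulate paired control/treated expression from planted effects
#'
#' Generative mirror of the scan models: for gene j and RIL r,
#' `y(r, cond) = mu + sum_i G_i beta_i (cis) + sum_i G_i gamma_i (trans, if
#' cond in scope) + delta 1(trt) + N(0, sigma^2)`, with `G_i` the soft founder
#' probabilities at the gene's planted marker. Both conditions are emitted
#' for every RIL.
#'
#' @param g [genotype_tensor].
#' @param truth [truth_table]; referenced markers must exist in `g`.
#' @param cfg [sim_config].
#' @return list: `expression` ([expression_matrix]) and `design`
#'   ([study_design]).
#' @export
simulate_expression_pair <- function(g, truth, cfg) {
  set.seed(derive_seed(cfg$seed, "expression"))
  mk <- c(truth$cis_marker, truth$trans_marker)
  bad <- !is.na(mk) & !(mk %in% g$map$marker_id)
  if (any(bad)) stop_input("truth table references unknown marker %s", mk[bad][1])
  n_r <- length(g$ril_ids)
  n_g <- nrow(truth)
  yc <- matrix(cfg$mu, n_r, n_g)
  yt <- matrix(cfg$mu, n_r, n_g)
  for (j in seq_len(n_g)) {
    if (!is.na(truth$cis_marker[j])) {
      eff <- drop(marker_probs(g, truth$cis_marker[j]) %*% truth$cis_effects[[j]])
      yc[, j] <- yc[, j] + eff
      yt[, j] <- yt[, j] + eff
    }
    if (!is.na(truth$trans_marker[j])) {
      eff <- drop(marker_probs(g, truth$trans_marker[j]) %*% truth$trans_effects[[j]])
      sc <- truth$trans_scope[j]
      if (sc %in% c("both", "ctrl-only")) yc[, j] <- yc[, j] + eff
      if (sc %in% c("both", "trt-only")) yt[, j] <- yt[, j] + eff
    }
    yt[, j] <- yt[, j] + truth$trt_effect[j]
  }
  yc <- yc + matrix(stats::rnorm(n_r * n_g, 0, cfg$sigma), n_r, n_g)
  yt <- yt + matrix(stats::rnorm(n_r * n_g, 0, cfg$sigma), n_r, n_g)
  m <- cbind(t(yc), t(yt))
  rownames(m) <- truth$gene_id
  colnames(m) <- c(paste0(g$ril_ids, "__ctrl"), paste0(g$ril_ids, "__trt"))
  x <- expression_matrix(m)
  list(expression = x, design = study_design(x))
}

scenario_names <- function() c("null", "cis_only", "hotspot_trt", "gxe", "mixed")

scenario_config <- function(scenario, seed) {
  switch(scenario,
    null = sim_config(n_rils = 60, markers_per_chrom = 40, n_genes = 300, seed = seed),
    cis_only = sim_config(n_rils = 79, markers_per_chrom = 40, n_genes = 200, seed = seed),
    hotspot_trt = sim_config(n_rils = 60, markers_per_chrom = 40, n_genes = 300,
                             crossovers_per_chrom = 2, seed = seed),
    gxe = sim_config(n_rils = 60, markers_per_chrom = 20, n_genes = 320, seed = seed),
    mixed = sim_config(n_rils = 60, markers_per_chrom = 40, n_genes = 200, seed = seed),
    stop_input("unknown scenario '%s'", scenario)
  )
}

# Random gene placement on the simulated genome; genes are 1 kb long.
place_genes <- function(cfg, map, gene_ids) {
  chrom <- sample(cfg$chroms, length(gene_ids), replace = TRUE)
  max_pos <- cfg$segment_bp * (cfg$markers_per_chrom + 1L)
  start <- as.integer(floor(stats::runif(length(gene_ids), 1, max_pos - 1000)))
  gene_annotation(data.frame(gene_id = gene_ids, chrom = chrom,
                             start_bp = start, end_bp = start + 999L,
                             strand = ".", stringsAsFactors = FALSE))
}

nearest_marker <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, ]
  sub$marker_id[which.min(abs(sub$pos_bp - pos))]
}

# Variance of the planted genetic signal relative to residual noise:
# heritability h2 means var(G beta) = sigma^2 * h2 / (1 - h2).
h2_to_var <- function(h2, sigma) sigma^2 * h2 / (1 - h2)

scenario_truth <- function(scenario, cfg, map, ann) {
  K <- length(cfg$founders)
  tt <- truth_table(ann$gene_id)
  if (scenario == "null") return(tt)
  if (scenario == "cis_only") {
    v <- h2_to_var(0.4, cfg$sigma)
    planted <- seq_len(40)
    for (j in planted) {
      mid <- (ann$start_bp[j] + ann$end_bp[j]) / 2
      tt$cis_marker[j] <- nearest_marker(map, ann$chrom[j], mid)
      tt$cis_effects[[j]] <- draw_founder_effects(K, v)
    }
    return(tt)
  }
  if (scenario == "hotspot_trt") {
    # trans effects are characteristically weaker than cis effects
    v <- h2_to_var(0.25, cfg$sigma)
    master <- map$marker_id[map$chrom == "2L"][ceiling(cfg$markers_per_chrom / 2)]
    targets <- seq_len(30)
    for (j in targets) {
      # targets must be distant (trans) from the master locus
      while (genetic_distance_cM(map, master, ann[j, ]) <= 5) {
        ann$chrom[j] <- sample(setdiff(cfg$chroms, "2L"), 1)
      }
      tt$trans_marker[j] <- master
      tt$trans_effects[[j]] <- draw_founder_effects(K, v)
      tt$trans_scope[j] <- "trt-only"
    }
    attr(tt, "annotation") <- ann
    return(tt)
  }
  if (scenario == "gxe") {
    v <- h2_to_var(0.5, cfg$sigma)
    planted <- seq_len(20)
    for (j in planted) {
      tt$trans_marker[j] <- sample(map$marker_id, 1)
      tt$trans_effects[[j]] <- draw_founder_effects(K, v)
      tt$trans_scope[j] <- "trt-only"
      tt$interaction[j] <- TRUE
    }
    return(tt)
  }
  if (scenario == "mixed") {
    vc <- h2_to_var(0.4, cfg$sigma)
    for (j in seq_len(20)) {
      mid <- (ann$start_bp[j] + ann$end_bp[j]) / 2
      tt$cis_marker[j] <- nearest_marker(map, ann$chrom[j], mid)
      tt$cis_effects[[j]] <- draw_founder_effects(K, vc)
    }
    master <- map$marker_id[map$chrom == "3R"][ceiling(cfg$markers_per_chrom / 2)]
    vt <- h2_to_var(0.25, cfg$sigma)
    for (j in 21:40) {
      while (genetic_distance_cM(map, master, ann[j, ]) <= 5) {
        ann$chrom[j] <- sample(setdiff(cfg$chroms, "3R"), 1)
      }
      tt$trans_marker[j] <- master
      tt$trans_effects[[j]] <- draw_founder_effects(K, vt)
      tt$trans_scope[j] <- "trt-only"
      tt$interaction[j] <- TRUE
    }
    tt$trt_effect <- stats::rnorm(nrow(tt), 0, 0.3)
    attr(tt, "annotation") <- ann
    return(tt)
  }
  stop_input("unknown scenario '%s'", scenario)
}

#' Simulate a complete study under a named scenario
#'
#' Scenarios: `null` (no planted effects), `cis_only` (40 local-effect genes),
#' `hotspot_trt` (one master locus trans-regulating 30 genes in the treated
#' condition only), `gxe` (20 genes with genotype-by-environment interaction
#' at gene-specific loci), and `mixed` (cis + treated-only hotspot +
#' treatment main effects).
#'
#' @param scenario scenario name.
#' @param seed master seed.
#' @return list with `config`, `map`, `genotypes`, `geno_truth`, `annotation`,
#'   `truth`, `expression`, `design`.
#' @export
simulate_scenario <- function(scenario, seed = 1L) {
  if (length(scenario) != 1 || !scenario %in% scenario_names()) {
    stop_input("unknown scenario '%s'", scenario)
  }
  cfg <- scenario_config(scenario, seed)
  sim <- simulate_ril_genotypes(cfg)
  map <- sim$genotypes$map
  set.seed(derive_seed(cfg$seed, paste0("plan_", scenario)))
  ann <- place_genes(cfg, map, sprintf("G%04d", seq_len(cfg$n_genes)))
  tt <- scenario_truth(scenario, cfg, map, ann)
  if (!is.null(attr(tt, "annotation"))) {
    ann <- attr(tt, "annotation")
    attr(tt, "annotation") <- NULL
  }
  ex <- simulate_expression_pair(sim$genotypes, tt, cfg)
  list(config = cfg, map = map, genotypes = sim$genotypes,
       geno_truth = sim$truth, annotation = ann, truth = tt,
       expression = ex$expression, design = ex$design)
}

#' Write / read a truth table TSV (effect vectors comma-joined)
#' @param tt [truth_table].
#' @param path file path.
#' @export
write_truth_table <- function(tt, path) {
  join <- function(lst) vapply(lst, function(v) {
    if (is.null(v)) NA_character_ else paste(fmt_num(v), collapse = ",")
  }, "")
  df <- data.frame(gene_id = tt$gene_id, cis_marker = tt$cis_marker,
                   cis_effects = join(tt$cis_effects),
                   trans_marker = tt$trans_marker,
                   trans_effects = join(tt$trans_effects),
                   trans_scope = tt$trans_scope, trt_effect = tt$trt_effect,
                   interaction = tt$interaction, stringsAsFactors = FALSE)
  write_tsv_exact(df, path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- read_tsv_raw(path)
  split_eff <- function(s) lapply(s, function(v) {
    if (is.na(v)) NULL else as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  truth_table(df$gene_id, cis_marker = df$cis_marker,
              cis_effects = split_eff(df$cis_effects),
              trans_marker = df$trans_marker,
              trans_effects = split_eff(df$trans_effects),
              trans_scope = df$trans_scope, trt_effect = df$trt_effect,
              interaction = df$interaction)
}

#' Write a complete simulated fixture to disk
#'
#' Emits `marker_map.tsv`, `genotype.tsv`, `expression.tsv`,
#' `annotation.tsv`, and `truth.tsv` in the package's TSV dialects.
#' Deterministic: the same (scenario, seed) always produces byte-identical
#' files.
#'
#' @param scenario scenario name (see [simulate_scenario]).
#' @param seed master seed.
#' @param dir output directory (created if absent).
#' @return invisibly, named vector of file paths.
#' @export
make_fixture_suite <- function(scenario, seed, dir) {
  sim <- simulate_scenario(scenario, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    marker_map = file.path(dir, "marker_map.tsv"),
    genotype = file.path(dir, "genotype.tsv"),
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_marker_map(sim$map, paths["marker_map"])
  write_genotype(sim$genotypes, paths["genotype"])
  write_expression(sim$expression, paths["expression"])
  write_gene_annotation(sim$annotation, paths["annotation"])
  write_truth_table(sim$truth, paths["truth"])
  invisible(paths)
}
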