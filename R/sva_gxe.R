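#' Estimate surrogate variables from expression heterogeneity
#'
#' Residualizes the expression matrix against the known design (treatment
#' indicator, optionally a RIL block) and takes leading left singular vectors
#' of the sample-space residual matrix as surrogate variables. With
#' `k = "auto"` the number of components is chosen by parallel analysis: a
#' component is kept when its singular value exceeds the 95th percentile of
#' the matched singular values of structureless same-size Gaussian matrices
#' drawn at the df-corrected residual noise scale and projected into the
#' residual subspace. (Permuting the observed residuals instead yields a
#' conditionally over-concentrated null that keeps spurious components far
#' more often than the nominal 5%.)
#'
#' @param x [expression_matrix] (normalized).
#' @param design [study_design] (used for the treatment indicator).
#' @param k integer number of surrogates, or `"auto"`.
#' @param seed RNG seed for the parallel-analysis null.
#' @param n_perm parallel-analysis replicates (default 20).
#' @param ril_block also residualize against RIL identity.
#' @return a `surrogate_variables`: list with `sv` (samples x k orthonormal,
#'   zero-mean columns; 0 columns when k = 0), `k`, `method`, `sample_id`.
#' @export
estimate_surrogates <- function(x, design = study_design(x), k = "auto",
                                seed = 1L, n_perm = 20, ril_block = FALSE) {
  s <- x$samples
  trt <- as.numeric(s$condition == "trt")
  X <- if (ril_block) stats::model.matrix(~ trt + factor(s$ril_id)) else cbind(1, trt)
  Y <- t(x$values)                       # samples x genes
  qx <- qr(X)
  R <- stats::residuals(stats::lm.fit(X, Y))   # samples x genes residuals
  max_k <- nrow(Y) - qx$rank
  if (is.numeric(k) && k > max_k) {
    stop_input("k = %d exceeds sample count minus design rank (%d)", k, max_k)
  }
  d_obs <- svd(R, nu = 0, nv = 0)$d
  if (identical(k, "auto")) {
    set.seed(seed)
    # parallel analysis against structureless matrices of the same size and
    # residual subspace; the df-corrected noise scale keeps the comparison
    # exchangeable with the observed singular values
    sigma_hat <- sqrt(sum(R^2) / ((nrow(Y) - qx$rank) * ncol(Y)))
    d_null <- matrix(0, n_perm, length(d_obs))
    for (b in seq_len(n_perm)) {
      Z <- matrix(stats::rnorm(length(R), 0, sigma_hat), nrow(Y), ncol(Y))
      d_null[b, ] <- svd(stats::residuals(stats::lm.fit(X, Z)), nu = 0, nv = 0)$d
    }
    thresh <- apply(d_null, 2, stats::quantile, probs = 0.95)
    keep <- d_obs > thresh
    k <- if (any(!keep)) min(which(!keep)) - 1L else length(d_obs)
    k <- min(k, max_k)
  }
  sv <- if (k > 0) svd(R, nu = k, nv = 0)$u else matrix(0, nrow(Y), 0)
  if (k > 0) sv <- sweep(sv, 2, colMeans(sv))  # centered; stays orthogonal
  structure(list(sv = sv, k = as.integer(k), method = "residual-svd",
                 sample_id = s$sample_id),
            class = "surrogate_variables")
}

build_gxe_design <- function(P, E, S, interaction = TRUE) {
  X <- cbind(1, S, P, E)
  if (interaction) X <- cbind(X, P * E)
  X
}

#' Interaction LOD at one marker
#'
#' Compares `H0: Y = mu + S + sum G_i + E + e` with
#' `H1: H0 + sum G_i * E`, fitted jointly over both conditions, and returns
#' `LOD = (n/2) log10(RSS0 / RSS1)`. The founder-probability blocks are rank
#' deficient (by at least 2 with the interaction block); RSS is computed from
#' orthonormal column bases so the deficiency resolution never matters.
#'
#' @param y per-sample response over both conditions.
#' @param G_m founder probability matrix per sample (RIL row duplicated
#'   across its two samples).
#' @param E environment indicator (0 = ctrl, 1 = trt) per sample.
#' @param S surrogate variable matrix per sample (or NULL).
#' @return interaction LOD (non-negative).
#' @export
gxe_lod <- function(y, G_m, E, S = NULL) {
  if (length(unique(E)) < 2) {
    stop_input("both conditions are required for an interaction fit")
  }
  S <- S %||% matrix(0, length(y), 0)
  q0 <- qr(build_gxe_design(G_m, E, S, interaction = FALSE))
  q1 <- qr(build_gxe_design(G_m, E, S, interaction = TRUE))
  Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
  Q1 <- qr.Q(q1)[, seq_len(q1$rank), drop = FALSE]
  tot <- sum(y^2)
  lod_from_rss(tot - sum(crossprod(Q0, y)^2), tot - sum(crossprod(Q1, y)^2),
               length(y))
}

gxe_lod_matrix <- function(g, Y, ril_of_sample, E, S) {
  # LOD (markers x genes) for all markers at once, stacking per-marker bases
  n_s <- nrow(Y)
  M <- nrow(g$map)
  tot <- colSums(Y^2)
  ri <- match(ril_of_sample, g$ril_ids)
  q0s <- vector("list", M); q1s <- vector("list", M)
  for (m in seq_len(M)) {
    P <- matrix(g$prob[, m, ], nrow = length(g$ril_ids))[ri, , drop = FALSE]
    qa <- qr(build_gxe_design(P, E, S, FALSE))
    qb <- qr(build_gxe_design(P, E, S, TRUE))
    q0s[[m]] <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
    q1s[[m]] <- qr.Q(qb)[, seq_len(qb$rank), drop = FALSE]
  }
  ss <- function(qs) {
    grp <- rep(seq_len(M), vapply(qs, ncol, 0L))
    f <- crossprod(do.call(cbind, qs), Y)
    rowsum(f * f, grp, reorder = TRUE)
  }
  rss0 <- sweep(-ss(q0s), 2, tot, "+")
  rss1 <- sweep(-ss(q1s), 2, tot, "+")
  lod <- (n_s / 2) * (log10(pmax(rss0, 1e-300)) - log10(pmax(rss1, 1e-300)))
  lod[lod < 0] <- 0
  rownames(lod) <- g$map$marker_id
  colnames(lod) <- colnames(Y)
  lod
}

#' Genome scan for genotype-by-environment interaction eQTLs
#'
#' Computes the interaction LOD ([gxe_lod]) for every gene at every marker
#' over both conditions jointly, then estimates gene-wise significance by
#' shuffling the condition labels within each RIL pair (preserving genotype
#' and pairing) and recording the genome-wide maximum interaction LOD per
#' replicate.
#'
#' @param x [expression_matrix].
#' @param g [genotype_tensor].
#' @param design [study_design]; only complete pairs are used.
#' @param S `surrogate_variables` (or NULL for none).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param smooth add-one smoothing of permutation p-values.
#' @return a `gxe_scan`: list with `lod`, `p` (markers x genes), `perm_max`,
#'   `map`, `n_perm`.
#' @export
gxe_scan <- function(x, g, design = study_design(x), S = NULL, n_perm = 1000,
                     seed = 1L, smooth = FALSE) {
  d <- design[design$paired, , drop = FALSE]
  if (!nrow(d)) stop_input("interaction scan requires paired samples")
  samples <- c(rbind(d$ctrl_sample, d$trt_sample))  # pair-adjacent ordering
  Y <- t(x$values[, samples, drop = FALSE])
  n_pair <- nrow(d)
  ril_of_sample <- rep(d$ril_id, each = 2)
  E <- rep(c(0, 1), n_pair)
  Sm <- if (is.null(S)) NULL else {
    si <- match(samples, S$sample_id)
    if (anyNA(si)) stop_input("surrogate variables do not cover all samples")
    S$sv[si, , drop = FALSE]
  }
  lod <- gxe_lod_matrix(g, Y, ril_of_sample, E, Sm)
  set.seed(seed)
  n_g <- ncol(Y)
  perm_max <- matrix(0, n_g, n_perm)
  for (b in seq_len(n_perm)) {
    flip <- sample(c(0, 1), n_pair, replace = TRUE)
    Eb <- as.numeric(xor(E, rep(flip, each = 2)))
    lp <- gxe_lod_matrix(g, Y, ril_of_sample, Eb, Sm)
    perm_max[, b] <- apply(lp, 2, max)
  }
  p <- matrix(0, nrow(lod), ncol(lod), dimnames = dimnames(lod))
  for (j in seq_len(n_g)) {
    cnt <- count_ge(lod[, j], sort(perm_max[j, ]))
    p[, j] <- if (smooth) (1 + cnt) / (1 + n_perm) else cnt / n_perm
  }
  structure(list(lod = lod, p = p, perm_max = perm_max, map = g$map,
                 n_perm = n_perm),
            class = "gxe_scan")
}

#' @export
print.gxe_scan <- function(x, ...) {
  cat(sprintf("gxe_scan: %d genes x %d markers, %d permutations\n",
              ncol(x$lod), nrow(x$lod), x$n_perm))
  invisible(x)
}
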