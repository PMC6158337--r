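#' Least-squares fit of expression on additive founder probabilities
#'
#' Fits `y = mu + sum_i G_i b_i + e` by least squares. Because the founder
#' probabilities sum to one at every RIL, the design `[1, G_1..G_K]` is rank
#' deficient by one; the minimum-norm solution is returned (via the SVD
#' pseudo-inverse). Only RSS-derived quantities are part of the public
#' contract — the residual sum of squares is invariant to how the deficiency
#' is resolved.
#'
#' @param y numeric response, one value per RIL.
#' @param G matrix of founder probabilities (RILs x K), or NULL for the
#'   intercept-only null model.
#' @return a `founder_fit`: list with `rss`, `n`, `mu`, `beta`, `rank`.
#' @export
fit_founder_regression <- function(y, G = NULL) {
  if (length(y) < 2) stop_input("need at least 2 observations")
  if (!all(is.finite(y))) stop_input("non-finite response values")
  X <- if (is.null(G)) matrix(1, length(y), 1) else cbind(1, as.matrix(G))
  if (nrow(X) != length(y)) stop_input("y and G dimensions disagree")
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  fitted <- X %*% beta
  structure(list(rss = sum((y - fitted)^2), n = length(y),
                 mu = beta[1], beta = drop(beta)[-1], rank = sum(pos)),
            class = "founder_fit")
}

#' LOD score from nested fits
#'
#' Gaussian maximum-likelihood identity for the likelihood ratio of the
#' genetic model over the intercept-only null:
#' `LOD = (n/2) * log10(RSS0 / RSS1)`. Negative values (possible only through
#' round-off) clip to 0; a perfect genetic fit (`RSS1 = 0` with `RSS0 > 0`)
#' returns `Inf`; a constant response (both RSS zero) returns 0.
#'
#' @param fit0 null-model `founder_fit`.
#' @param fit1 genetic-model `founder_fit` on the same data.
#' @return LOD score (non-negative, possibly `Inf`).
#' @export
lod_from_fits <- function(fit0, fit1) {
  if (fit0$n != fit1$n) stop_input("fits do not share the same samples")
  lod_from_rss(fit0$rss, fit1$rss, fit0$n)
}

lod_from_rss <- function(rss0, rss1, n) {
  eps <- 1e-12
  if (rss0 <= eps && rss1 <= eps) return(0)
  if (rss1 <= eps) return(Inf)
  max(0, (n / 2) * log10(rss0 / rss1))
}

# Precompute, for every marker, an orthonormal basis of the column space of
# [1, G_1..G_K], stacked into one matrix so that fitted sums of squares for
# all genes and markers reduce to a single BLAS product.
scan_engine <- function(g, markers = NULL) {
  map <- g$map
  idx <- if (is.null(markers)) seq_len(nrow(map)) else match(markers, map$marker_id)
  if (anyNA(idx)) stop_input("unknown marker in scan request")
  n <- length(g$ril_ids)
  qs <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    X <- cbind(1, matrix(g$prob[, idx[i], ], nrow = n))
    qr_x <- qr(X)
    qs[[i]] <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  }
  ranks <- vapply(qs, ncol, 0L)
  list(Qt = t(do.call(cbind, qs)),                 # sum(ranks) x n
       group = rep(seq_along(idx), ranks),
       marker_id = map$marker_id[idx], n = n)
}

# Fitted (model) sums of squares per (marker, gene): markers x genes matrix.
engine_fit_ss <- function(eng, Y) {
  f <- eng$Qt %*% Y
  rowsum(f * f, eng$group, reorder = TRUE)
}

# LOD matrix (markers x genes) for a RILs x genes response matrix.
lod_matrix <- function(eng, Y) {
  tot <- colSums(Y^2)
  rss0 <- tot - nrow(Y) * colMeans(Y)^2
  ss1 <- engine_fit_ss(eng, Y)
  rss1 <- sweep(-ss1, 2, tot, "+")
  lod <- (eng$n / 2) * (log10(pmax(rss0[col(rss1)], 1e-300)) - log10(pmax(rss1, 1e-300)))
  lod[rss1 <= 1e-12] <- Inf
  lod[, rss0 <= 1e-12] <- 0
  lod[lod < 0] <- 0
  rownames(lod) <- eng$marker_id
  colnames(lod) <- colnames(Y)
  lod
}

#' LOD profile of one gene across all markers
#'
#' @param y per-RIL expression values, ordered as `g$ril_ids` (or named).
#' @param g [genotype_tensor].
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `cM`, `lod`.
#' @export
scan_gene <- function(y, g) {
  if (!is.null(names(y))) {
    if (!setequal(names(y), g$ril_ids)) stop_input("RILs of y do not match genotypes")
    y <- y[g$ril_ids]
  } else if (length(y) != length(g$ril_ids)) {
    stop_input("y length does not match RIL count")
  }
  eng <- scan_engine(g)
  lod <- lod_matrix(eng, matrix(y, ncol = 1))
  data.frame(marker_id = g$map$marker_id, chrom = g$map$chrom,
             pos_bp = g$map$pos_bp, cM = g$map$cM, lod = drop(lod),
             stringsAsFactors = FALSE)
}

# Count, for each observed value, how many null draws are >= it.
count_ge <- function(obs, null_sorted) {
  length(null_sorted) - findInterval(obs, null_sorted, left.open = TRUE)
}

#' Gene-wise permutation p-values for one gene
#'
#' Shuffles the gene's expression values across RILs and records the
#' genome-wide maximum LOD of each shuffled replicate (one number per
#' permutation). The p-value at each marker is the fraction of permutation
#' maxima at or above the observed LOD there (plug-in estimator; with
#' `smooth = TRUE`, `(1 + b) / (1 + B)`).
#'
#' @param y per-RIL expression values.
#' @param g [genotype_tensor].
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed.
#' @param smooth use the add-one smoothed estimator.
#' @param per_locus_null compare each marker against its own permutation
#'   distribution instead of the genome-wide maximum.
#' @return data.frame `marker_id`, `lod`, `p`.
#' @export
permutation_pvalues <- function(y, g, n_perm = 1000, seed = 1L, smooth = FALSE,
                                per_locus_null = FALSE) {
  if (n_perm < 100) stop_input("n_perm must be at least 100")
  prof <- scan_gene(y, g)
  eng <- scan_engine(g)
  set.seed(seed)
  n <- length(g$ril_ids)
  yv <- if (!is.null(names(y))) y[g$ril_ids] else y
  null_lod <- matrix(0, nrow(g$map), n_perm)
  for (b in seq_len(n_perm)) {
    null_lod[, b] <- lod_matrix(eng, matrix(yv[sample.int(n)], ncol = 1))
  }
  if (per_locus_null) {
    cnt <- vapply(seq_len(nrow(null_lod)), function(m) {
      sum(null_lod[m, ] >= prof$lod[m])
    }, 0L)
  } else {
    maxima <- sort(apply(null_lod, 2, max))
    cnt <- count_ge(prof$lod, maxima)
  }
  prof$p <- if (smooth) (1 + cnt) / (1 + n_perm) else cnt / n_perm
  prof
}

#' Genome scan of all genes in one condition, with permutation significance
#'
#' Runs the founder-probability regression LOD scan for every gene at every
#' marker, then estimates gene-wise significance by permutation: per
#' replicate the RIL labels of each gene's expression are shuffled (within
#' the condition) and the genome-wide maximum LOD is recorded, giving each
#' gene its own genome-wide-corrected null.
#'
#' @param x [expression_matrix] (normalized).
#' @param g [genotype_tensor].
#' @param condition `"ctrl"` or `"trt"`.
#' @param n_perm permutations per gene (default 1000).
#' @param seed RNG seed.
#' @param smooth add-one smoothing of permutation p-values.
#' @return an `eqtl_scan`: list with `lod` and `p` (markers x genes),
#'   `perm_max` (genes x n_perm), `condition`, `map`, `n_perm`.
#' @export
scan_condition <- function(x, g, condition = c("ctrl", "trt"), n_perm = 1000,
                           seed = 1L, smooth = FALSE) {
  condition <- match.arg(condition)
  Ym <- condition_matrix(x, condition, g$ril_ids)   # genes x rils
  Y <- t(Ym)                                        # rils x genes
  eng <- scan_engine(g)
  lod <- lod_matrix(eng, Y)
  set.seed(seed)
  n <- nrow(Y)
  n_g <- ncol(Y)
  perm_max <- matrix(0, n_g, n_perm)
  for (b in seq_len(n_perm)) {
    lp <- lod_matrix(eng, Y[sample.int(n), , drop = FALSE])
    perm_max[, b] <- apply(lp, 2, max)
  }
  p <- matrix(0, nrow(lod), ncol(lod), dimnames = dimnames(lod))
  for (j in seq_len(n_g)) {
    cnt <- count_ge(lod[, j], sort(perm_max[j, ]))
    p[, j] <- if (smooth) (1 + cnt) / (1 + n_perm) else cnt / n_perm
  }
  structure(list(lod = lod, p = p, perm_max = perm_max,
                 condition = condition, map = g$map, n_perm = n_perm),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("eqtl_scan (%s): %d genes x %d markers, %d permutations\n",
              x$condition, ncol(x$lod), nrow(x$lod), x$n_perm))
  invisible(x)
}

#' Significant (gene, marker) associations from a scan
#'
#' @param scan an `eqtl_scan`.
#' @param alpha permutation p-value cutoff (default 0.05).
#' @return data.frame `gene_id`, `marker_id`, `condition`, `lod`, `p`, `q`
#'   (q-values over the full scan's p-values).
#' @export
significant_hits <- function(scan, alpha = 0.05) {
  q <- matrix(storey_qvalue(as.vector(scan$p)), nrow(scan$p), ncol(scan$p))
  sel <- which(scan$p <= alpha, arr.ind = TRUE)
  out <- data.frame(
    gene_id = colnames(scan$p)[sel[, 2]],
    marker_id = rownames(scan$p)[sel[, 1]],
    condition = scan$condition,
    lod = scan$lod[sel], p = scan$p[sel], q = q[sel],
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, match(out$marker_id, scan$map$marker_id)), , drop = FALSE]
}

#' Storey q-values
#'
#' The null proportion pi0 is estimated by smoothing `pi0(lambda) =
#' mean(p > lambda) / (1 - lambda)` over the grid `lambda = 0.05..0.95` step
#' 0.05 with a cubic smoothing spline evaluated at the largest lambda,
#' falling back to `pi0 = 1` when the estimate exceeds 1 or fewer than 100
#' p-values are supplied. Then `q_i = min over p_j >= p_i of
#' pi0 * m * p_j / rank(p_j)`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
storey_qvalue <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_input("p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (m < 100) {
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    if (!is.finite(pi0) || pi0 > 1) pi0 <- 1
    pi0 <- max(pi0, 1e-8)
  }
  o <- order(p, decreasing = TRUE)
  ranks <- rank(p, ties.method = "max")
  q <- pi0 * m * p / ranks
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

#' Classify significant hits as cis or trans
#'
#' A hit is cis when the genetic distance between its marker and the gene
#' midpoint is at most `cis_cM` (inclusive at the boundary), trans otherwise;
#' cross-chromosome hits are always trans. Genes absent from the annotation
#' are skipped with a warning.
#'
#' @param hits data.frame with `gene_id`, `marker_id` (from
#'   [significant_hits]).
#' @param ann [gene_annotation].
#' @param map [marker_map].
#' @param cis_cM cis boundary in cM (default 1, inclusive).
#' @return `hits` with added `distance_cM` and `class` columns.
#' @export
classify_cis_trans <- function(hits, ann, map, cis_cM = 1.0) {
  known <- hits$gene_id %in% ann$gene_id
  if (!all(known)) {
    warning(sprintf("skipping %d hits for unannotated genes", sum(!known)))
    hits <- hits[known, , drop = FALSE]
  }
  if (!nrow(hits)) {
    hits$distance_cM <- numeric(0)
    hits$class <- character(0)
    return(hits)
  }
  hits$distance_cM <- genetic_distance_many(map, hits$marker_id, ann, hits$gene_id)
  hits$class <- ifelse(hits$distance_cM <= cis_cM, "cis", "trans")
  hits
}

#' Gene-level condition specificity of eQTL classes
#'
#' Per gene and class (cis/trans), compares which conditions carry at least
#' one significant hit: `shared` when both do, otherwise `ctrl-specific` or
#' `trt-specific`.
#'
#' @param hits_ctrl,hits_trt classified hit tables from the two condition
#'   scans (same gene/marker universe).
#' @return data.frame `gene_id`, `class`, `specificity`.
#' @export
condition_specificity <- function(hits_ctrl, hits_trt) {
  key <- function(h) unique(h[, c("gene_id", "class")])
  a <- key(hits_ctrl); a$in_ctrl <- rep(TRUE, nrow(a))
  b <- key(hits_trt); b$in_trt <- rep(TRUE, nrow(b))
  mrg <- merge(a, b, by = c("gene_id", "class"), all = TRUE)
  mrg$in_ctrl <- !is.na(mrg$in_ctrl)
  mrg$in_trt <- !is.na(mrg$in_trt)
  mrg$specificity <- ifelse(mrg$in_ctrl & mrg$in_trt, "shared",
                            ifelse(mrg$in_ctrl, "ctrl-specific", "trt-specific"))
  mrg[order(mrg$gene_id, mrg$class), c("gene_id", "class", "specificity")]
}
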