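qn_target_assign <- function(v, target) {
  # sorted values replaced by target; ties receive the mean of their target
  # quantiles, which keeps the result invariant to input permutation
  out <- numeric(length(v))
  out[order(v)] <- target
  stats::ave(out, factor(v), FUN = mean)
}

qn_columns <- function(m) {
  target <- rowMeans(apply(m, 2, sort))
  apply(m, 2, qn_target_assign, target = target)
}

#' Two-pass quantile normalization
#'
#' Pass 1 normalizes each sample column to the average empirical distribution
#' across all samples; pass 2 applies the same procedure gene-wise (each gene
#' row mapped to the average distribution across genes). After pass 1 every
#' sample column carries an identical multiset of values. The operator is
#' only approximately idempotent: the gene-wise pass re-arranges values so a
#' repeat application moves them again, by an amount that shrinks as the gene
#' count grows.
#'
#' @param x [expression_matrix] (no missing values).
#' @param log2_counts if TRUE, apply `log2(x + 1)` first (raw count input).
#' @return normalized [expression_matrix] of the same shape.
#' @export
quantile_normalize_two_pass <- function(x, log2_counts = FALSE) {
  m <- x$values
  if (log2_counts) m <- log2(m + 1)
  p1 <- qn_columns(m)
  p2 <- t(qn_columns(t(p1)))
  dimnames(p2) <- dimnames(m)
  expression_matrix(p2)
}

#' Paired differential expression with RIL as covariate
#'
#' Per gene, ordinary least squares of expression on a treatment indicator
#' plus a RIL indicator block (`Y ~ treatment + RIL`), equivalent to a paired
#' analysis. The treatment coefficient is the log2 fold change
#' (treated minus control); two-sided p-values come from the coefficient's t
#' statistic and are converted to q-values with [storey_qvalue].
#'
#' @param x [expression_matrix] of log2-scale values.
#' @param design [study_design]; at least 3 complete RIL pairs required.
#' @return data.frame: `gene_id`, `log2fc`, `t`, `p`, `q`.
#' @export
differential_expression_paired <- function(x, design = study_design(x)) {
  d <- design[design$paired, , drop = FALSE]
  if (nrow(d) == 0) {
    stop_input("no complete RIL pairs; unpaired designs are unsupported")
  }
  if (nrow(d) < 3) stop_input("need at least 3 complete RIL pairs")
  samples <- c(d$ctrl_sample, d$trt_sample)
  Y <- t(x$values[, samples, drop = FALSE])        # samples x genes
  trt <- rep(c(0, 1), each = nrow(d))
  ril <- factor(rep(d$ril_id, 2))
  X <- stats::model.matrix(~ trt + ril)
  fit <- stats::lm.fit(X, Y)
  df_res <- nrow(X) - fit$rank
  rss <- colSums(fit$residuals^2)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  v_trt <- xtx_inv[2, 2]
  beta <- fit$coefficients["trt", ]
  se <- sqrt(rss / df_res * v_trt)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  data.frame(gene_id = rownames(x$values), log2fc = unname(beta),
             t = unname(tstat), p = unname(p), q = storey_qvalue(p),
             stringsAsFactors = FALSE)
}
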