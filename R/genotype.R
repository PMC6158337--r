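#' Construct a genotype tensor
#'
#' Founder-origin probabilities for every (RIL, marker, founder) triple: the
#' additive genotype predictors of the haplotype regression. Each RIL is a
#' homozygous mosaic of the founders, so at every marker the probabilities
#' over founders sum to one.
#'
#' @param prob 3-d array `[ril, marker, founder]` with dimnames.
#' @param map [marker_map] matching the marker dimension.
#' @return a `genotype_tensor`: list with `prob`, `ril_ids`, `founders`, `map`.
#' @export
genotype_tensor <- function(prob, map) {
  stopifnot(is.array(prob), length(dim(prob)) == 3)
  dn <- dimnames(prob)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop_input("genotype probability array needs full dimnames")
  }
  if (!identical(dn[[2]], map$marker_id)) {
    stop_input("marker dimension does not match marker map")
  }
  if (dim(prob)[3] < 2) stop_input("need at least 2 founders")
  if (any(prob < -1e-9 | prob > 1 + 1e-9)) stop_input("probabilities outside [0,1]")
  sums <- apply(prob, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop_input("founder probabilities do not sum to 1 (max dev %.3g)",
               max(abs(sums - 1)))
  }
  structure(
    list(prob = prob, ril_ids = dn[[1]], founders = dn[[3]], map = map),
    class = "genotype_tensor"
  )
}

#' @export
print.genotype_tensor <- function(x, ...) {
  cat(sprintf("genotype_tensor: %d RILs x %d markers x %d founders (%s)\n",
              length(x$ril_ids), nrow(x$map), length(x$founders),
              paste(unique(x$map$chrom), collapse = ", ")))
  invisible(x)
}

# RIL x founder probability matrix at one marker.
marker_probs <- function(g, marker_id) {
  j <- match(marker_id, g$map$marker_id)
  if (is.na(j)) stop_input("unknown marker_id %s", marker_id)
  p <- g$prob[, j, , drop = TRUE]
  matrix(p, nrow = length(g$ril_ids), ncol = length(g$founders),
         dimnames = list(g$ril_ids, g$founders))
}

#' Read founder genotype probabilities from long-format TSV
#'
#' Dialect: header `ril_id  marker_id  p_<F1> ... p_<FK>`; one row per
#' (RIL, marker). Probability rows are renormalized when their sum is within
#' 1e-3 of one, and rejected otherwise.
#'
#' @param path file path.
#' @param map [marker_map] giving the marker universe and order.
#' @return [genotype_tensor].
#' @export
read_genotype <- function(path, map) {
  df <- read_tsv_raw(path)
  pcols <- grep("^p_", names(df), value = TRUE)
  if (length(pcols) < 2) stop_input("genotype file has fewer than 2 founder columns")
  founders <- sub("^p_", "", pcols)
  mi <- match(df$marker_id, map$marker_id)
  if (anyNA(mi)) {
    stop_input("unknown marker_id '%s' at line %d",
               df$marker_id[which(is.na(mi))[1]], which(is.na(mi))[1] + 1L)
  }
  pm <- as.matrix(df[, pcols])
  sums <- rowSums(pm)
  off <- abs(sums - 1) > 1e-3
  if (any(off)) {
    stop_input("founder probabilities sum to %.4f at line %d",
               sums[which(off)[1]], which(off)[1] + 1L)
  }
  pm <- pm / sums
  rils <- unique(df$ril_id)
  prob <- array(NA_real_, dim = c(length(rils), nrow(map), length(founders)),
                dimnames = list(rils, map$marker_id, founders))
  ri <- match(df$ril_id, rils)
  for (k in seq_along(founders)) {
    prob[cbind(ri, mi, k)] <- pm[, k]
  }
  if (anyNA(prob)) stop_input("genotype file is missing (ril, marker) rows")
  genotype_tensor(prob, map)
}

#' Write founder genotype probabilities to long-format TSV
#' @param g [genotype_tensor].
#' @param path output file path.
#' @export
write_genotype <- function(g, path) {
  n_r <- length(g$ril_ids); n_m <- nrow(g$map)
  df <- data.frame(
    ril_id = rep(g$ril_ids, each = n_m),
    marker_id = rep(g$map$marker_id, times = n_r),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(g$founders)) {
    df[[paste0("p_", g$founders[k])]] <- as.vector(t(g$prob[, , k]))
  }
  write_tsv_exact(df, path)
}

#' Hard founder calls at a marker
#'
#' Assigns each RIL the founder with the highest probability at the marker,
#' or `"ambiguous"` when the top probability falls below `min_prob` or is
#' tied. Used to color samples by parental origin when displaying hotspot
#' expression patterns.
#'
#' @param g [genotype_tensor].
#' @param marker_id marker to call.
#' @param min_prob minimum winning probability (default 0.8).
#' @return named character vector (one call per RIL).
#' @export
founder_hard_call <- function(g, marker_id, min_prob = 0.8) {
  p <- marker_probs(g, marker_id)
  top <- apply(p, 1, max)
  n_top <- rowSums(abs(p - top) < 1e-12)
  idx <- apply(p, 1, which.max)
  call <- g$founders[idx]
  call[top < min_prob | n_top > 1] <- "ambiguous"
  stats::setNames(call, g$ril_ids)
}
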