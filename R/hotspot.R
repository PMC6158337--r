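#' Distant (trans) hit indicator matrix
#'
#' Binary markers x genes matrix with 1 where the gene's permutation p-value
#' is at or below `alpha` AND the marker lies more than `distant_cM` from the
#' gene on the genetic map (cross-chromosome is always distant). Hits within
#' the local window never contribute to hotspot band counts.
#'
#' @param scan an `eqtl_scan`.
#' @param ann [gene_annotation].
#' @param alpha eQTL p-value cutoff (default 0.05).
#' @param distant_cM local exclusion radius in cM (default 1, the cis rule).
#' @return binary matrix (markers x genes).
#' @export
distant_hit_matrix <- function(scan, ann, alpha = 0.05, distant_cM = 1.0) {
  map <- scan$map
  genes <- colnames(scan$p)
  gi <- match(genes, ann$gene_id)
  if (anyNA(gi)) stop_input("scan genes missing from annotation")
  D <- (scan$p <= alpha) * 1L
  for (j in seq_along(genes)) {
    if (!any(D[, j])) next
    d <- genetic_distance_many(map, map$marker_id, ann, rep(genes[j], nrow(map)))
    D[d <= distant_cM, j] <- 0L
  }
  D
}

#' Per-marker associated-gene counts (band counts)
#'
#' @param D binary distant-hit matrix (markers x genes).
#' @return integer vector: number of distant associated genes per marker.
#' @export
band_counts <- function(D) {
  stats::setNames(as.integer(rowSums(D)), rownames(D))
}

#' Band-permutation null distribution of hotspot counts
#'
#' Per replicate, each gene's distant-hit indicator row is independently
#' permuted across markers (preserving the gene's number of distant hits) and
#' band counts are recomputed. With `pooled = TRUE` (default) all per-marker
#' counts across replicates form one exchangeable null; with
#' `block = TRUE` one shared marker permutation per replicate is used
#' instead, preserving gene-gene correlation (sensitivity mode).
#'
#' @param D binary distant-hit matrix (markers x genes).
#' @param n_perm number of replicates (>= 100; default 1000).
#' @param seed RNG seed.
#' @param block use one shared permutation per replicate.
#' @return a `band_null`: list with `counts` (markers x n_perm matrix of null
#'   band counts) and `pooled` (sorted vector of all null counts).
#' @export
band_null <- function(D, n_perm = 1000, seed = 1L, block = FALSE) {
  if (n_perm < 100) stop_input("n_perm must be at least 100")
  set.seed(seed)
  M <- nrow(D)
  hit_pos <- apply(D, 2, function(col) which(col == 1L), simplify = FALSE)
  n_hits <- lengths(hit_pos)
  counts <- matrix(0L, M, n_perm)
  for (b in seq_len(n_perm)) {
    if (block) {
      perm <- sample.int(M)
      pos <- unlist(lapply(hit_pos, function(idx) perm[idx]), use.names = FALSE)
    } else {
      pos <- unlist(lapply(n_hits, function(k) sample.int(M, k)), use.names = FALSE)
    }
    counts[, b] <- tabulate(pos, nbins = M)
  }
  structure(list(counts = counts, pooled = sort(as.vector(counts))),
            class = "band_null")
}

#' Permutation-based hotspot p-values
#'
#' `p(m)` is the fraction of null band counts at or above the observed count
#' at marker `m`; markers with `p <= 0.05` are candidate hotspot peaks.
#'
#' @param counts observed band counts ([band_counts]).
#' @param null a `band_null`.
#' @param pooled compare against the pooled null (default) or each marker's
#'   own null distribution.
#' @return named numeric vector of hotspot p-values.
#' @export
hotspot_pvalues <- function(counts, null, pooled = TRUE) {
  if (pooled) {
    nv <- null$pooled
    p <- count_ge(counts, nv) / length(nv)
  } else {
    p <- vapply(seq_along(counts), function(m) {
      mean(null$counts[m, ] >= counts[m])
    }, 0)
  }
  stats::setNames(p, names(counts))
}

cond_lod_pair <- function(Y, PA, PB) {
  # conditional LOD of peak B given peak A, per gene: joint model [1, GA, GB]
  # against single-peak model [1, GA]
  n <- nrow(Y)
  qa <- qr(cbind(1, PA)); Qa <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
  qab <- qr(cbind(1, PA, PB)); Qab <- qr.Q(qab)[, seq_len(qab$rank), drop = FALSE]
  tot <- colSums(Y^2)
  rss_a <- tot - colSums((crossprod(Qa, Y))^2)
  rss_ab <- tot - colSums((crossprod(Qab, Y))^2)
  (n / 2) * log10(pmax(rss_a, 1e-300) / pmax(rss_ab, 1e-300))
}

#' Merge adjacent hotspot peaks with shared downstream influence
#'
#' For each pair of candidate peaks within `window_cM` on one chromosome, and
#' for each gene associated with both, compares the joint two-locus model to
#' the single-locus model; when the median conditional LOD of the second peak
#' given the first falls below `merge_lod` across the shared genes, the peaks
#' are not genetically separable and are combined. Group membership is the
#' transitive closure of pairwise merges.
#'
#' @param peaks character vector of candidate peak marker ids (hotspot
#'   p <= 0.05), in map order.
#' @param D binary distant-hit matrix.
#' @param g [genotype_tensor].
#' @param Y RILs x genes expression matrix for the scanned condition
#'   (columns matching `colnames(D)`).
#' @param window_cM how far apart peaks may sit and still be tested for
#'   merging (default 5 cM).
#' @param merge_lod conditional-LOD threshold below which peaks merge
#'   (default 1.5).
#' @return list of character vectors, each one merged group of peak markers.
#' @export
merge_adjacent <- function(peaks, D, g, Y, window_cM = 5, merge_lod = 1.5) {
  map <- g$map
  peaks <- peaks[order(match(peaks, map$marker_id))]
  n_p <- length(peaks)
  if (n_p <= 1) return(if (n_p) list(peaks) else list())
  pi_ <- match(peaks, map$marker_id)
  parent <- seq_len(n_p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(n_p - 1)) {
    for (b in (a + 1):n_p) {
      if (map$chrom[pi_[a]] != map$chrom[pi_[b]]) next
      if (abs(map$cM[pi_[a]] - map$cM[pi_[b]]) > window_cM) next
      shared <- which(D[pi_[a], ] == 1L & D[pi_[b], ] == 1L)
      if (!length(shared)) next
      Ys <- Y[, shared, drop = FALSE]
      Pa <- marker_probs(g, peaks[a]); Pb <- marker_probs(g, peaks[b])
      # separability is symmetric: peaks combine when either adds nothing
      # beyond the other for the genes they share
      cl <- pmin(cond_lod_pair(Ys, Pa, Pb), cond_lod_pair(Ys, Pb, Pa))
      if (stats::median(cl) < merge_lod) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n_p), find, 0L)
  lapply(split(peaks, roots), identity)
}

#' Assemble hotspot regions from merged peak groups
#'
#' Each group becomes one hotspot: the peak is the member marker with the
#' largest band count (ties break to the leftmost); the region spans the
#' outermost contiguous run of hotspot-significant markers around the peak;
#' the gene list holds the distinct genes associated at the peak.
#'
#' @param groups list of peak-marker groups ([merge_adjacent]).
#' @param D binary distant-hit matrix.
#' @param pvals hotspot p-values per marker ([hotspot_pvalues]).
#' @param map [marker_map].
#' @param condition condition label to record.
#' @param alpha hotspot p-value cutoff defining the significant run
#'   (default 0.05).
#' @return data.frame: `condition`, `chrom`, `start_marker`, `end_marker`,
#'   `peak_marker`, `start_bp`, `end_bp`, `peak_bp`, `n_genes`, `p`,
#'   `genes` (comma-joined).
#' @export
hotspot_regions <- function(groups, D, pvals, map, condition, alpha = 0.05) {
  counts <- band_counts(D)
  rows <- lapply(groups, function(members) {
    mi <- match(members, map$marker_id)
    cnt <- counts[mi]
    peak_i <- mi[which.max(cnt)]   # which.max takes the first (leftmost) tie
    ch <- map$chrom[peak_i]
    on_ch <- which(map$chrom == ch)
    sig <- pvals[on_ch] <= alpha
    pos <- match(peak_i, on_ch)
    lo <- pos; while (lo > 1 && sig[lo - 1]) lo <- lo - 1
    hi <- pos; while (hi < length(on_ch) && sig[hi + 1]) hi <- hi + 1
    lo <- min(lo, match(mi[1], on_ch))
    hi <- max(hi, match(mi[length(mi)], on_ch))
    genes <- colnames(D)[D[peak_i, ] == 1L]
    data.frame(condition = condition, chrom = ch,
               start_marker = map$marker_id[on_ch[lo]],
               end_marker = map$marker_id[on_ch[hi]],
               peak_marker = map$marker_id[peak_i],
               start_bp = map$pos_bp[on_ch[lo]],
               end_bp = map$pos_bp[on_ch[hi]],
               peak_bp = map$pos_bp[peak_i],
               n_genes = length(genes),
               p = unname(pvals[peak_i]),
               genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(condition = character(0), chrom = character(0),
                      start_marker = character(0), end_marker = character(0),
                      peak_marker = character(0), start_bp = integer(0),
                      end_bp = integer(0), peak_bp = integer(0),
                      n_genes = integer(0), p = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(match(out$peak_marker, map$marker_id)), , drop = FALSE]
}

#' Detect trans-eQTL hotspots for one condition scan
#'
#' Full hotspot stage: distant-hit matrix, band counts, band-permutation
#' null, hotspot p-values, merging of nearby non-separable peaks, and region
#' assembly.
#'
#' @param scan an `eqtl_scan`.
#' @param ann [gene_annotation].
#' @param g [genotype_tensor].
#' @param x [expression_matrix] (for the conditional-LOD merge fits).
#' @param alpha eQTL significance cutoff for distant hits (default 0.05).
#' @param distant_cM local exclusion radius (default 1 cM).
#' @param n_perm band-permutation replicates (default 1000).
#' @param seed RNG seed.
#' @param window_cM merge window (default 5 cM).
#' @param merge_lod conditional-LOD merge threshold (default 1.5).
#' @param hotspot_alpha hotspot p-value cutoff (default 0.05).
#' @return list: `hotspots` (region table), `counts`, `pvalues`, `D`, `null`.
#' @export
detect_hotspots <- function(scan, ann, g, x, alpha = 0.05, distant_cM = 1.0,
                            n_perm = 1000, seed = 1L, window_cM = 5,
                            merge_lod = 1.5, hotspot_alpha = 0.05) {
  D <- distant_hit_matrix(scan, ann, alpha, distant_cM)
  counts <- band_counts(D)
  null <- band_null(D, n_perm = n_perm, seed = seed)
  pvals <- hotspot_pvalues(counts, null)
  cand_all <- names(pvals)[pvals <= hotspot_alpha]
  cand <- cand_all[counts[cand_all] > 0]
  if (length(cand) < length(cand_all)) {
    warning("dropping candidate peaks without associated genes")
  }
  Y <- t(condition_matrix(x, scan$condition, g$ril_ids))
  groups <- merge_adjacent(cand, D, g, Y, window_cM, merge_lod)
  hotspots <- hotspot_regions(groups, D, pvals, g$map, scan$condition, hotspot_alpha)
  list(hotspots = hotspots, counts = counts, pvalues = pvals, D = D, null = null)
}

#' Flag hotspots as shared or condition-specific
#'
#' A hotspot is `shared` when the other condition has a hotspot whose region
#' overlaps it on the same chromosome, otherwise `ctrl-only` / `trt-only`.
#'
#' @param h_ctrl,h_trt hotspot region tables ([hotspot_regions]).
#' @return combined table with a `specificity` column.
#' @export
compare_hotspots <- function(h_ctrl, h_trt) {
  overlaps <- function(a, b) {
    any(b$chrom == a$chrom & b$start_bp <= a$end_bp & b$end_bp >= a$start_bp)
  }
  flag <- function(h, other, own_label) {
    if (!nrow(h)) return(character(0))
    vapply(seq_len(nrow(h)), function(i) {
      if (nrow(other) && overlaps(h[i, ], other)) "shared" else own_label
    }, "")
  }
  h_ctrl$specificity <- flag(h_ctrl, h_trt, "ctrl-only")
  h_trt$specificity <- flag(h_trt, h_ctrl, "trt-only")
  rbind(h_ctrl, h_trt)
}
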