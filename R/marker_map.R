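#' Construct a validated marker map
#'
#' A marker map places genotyped markers on both the physical (bp) and the
#' genetic (cM) scale. Markers sit at the junctions between fixed-width
#' genomic segments, following the convention of multi-founder RIL panels
#' whose founder-origin probabilities are reported per 10-kb segment.
#'
#' @param df data.frame with columns `marker_id`, `chrom`, `pos_bp`, `cM`.
#' @return A `marker_map` (data.frame subclass) sorted by chromosome and
#'   position, with unique marker ids, strictly increasing `pos_bp` and
#'   non-decreasing `cM` within each chromosome.
#' @export
marker_map <- function(df) {
  need <- c("marker_id", "chrom", "pos_bp", "cM")
  if (!all(need %in% names(df))) {
    stop_input("marker map needs columns: %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  df$pos_bp <- as.integer(df$pos_bp)
  df$cM <- as.numeric(df$cM)
  if (anyNA(df)) stop_input("marker map contains missing values")
  if (anyDuplicated(df$marker_id)) stop_input("duplicated marker_id in marker map")
  if (any(df$cM < 0)) stop_input("negative cM in marker map")
  blocks <- rle(df$chrom)$values
  if (anyDuplicated(blocks)) {
    stop_input("chromosome rows must be contiguous in the marker map")
  }
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1) {
      if (any(diff(sub$pos_bp) <= 0)) {
        stop_input("pos_bp not strictly increasing on chrom %s", ch)
      }
      if (any(diff(sub$cM) < 0)) {
        stop_input("cM decreasing on chrom %s", ch)
      }
    }
  }
  # row order is preserved: files are required to arrive position-sorted
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read a marker map from TSV
#'
#' Dialect: header `marker_id  chrom  pos_bp  cM`, tab-separated, `NA` for
#' missing (not allowed in a valid map).
#'
#' @param path file path.
#' @return validated [marker_map].
#' @export
read_marker_map <- function(path) {
  df <- tryCatch(read_tsv_raw(path), error = function(e) {
    stop_input("cannot parse marker map %s: %s", path, conditionMessage(e))
  })
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop_input("malformed marker map row at line %d of %s", bad[1] + 1L, path)
  }
  marker_map(df)
}

#' Write a marker map to TSV
#' @param map a [marker_map].
#' @param path output file path.
#' @export
write_marker_map <- function(map, path) {
  write_tsv_exact(as.data.frame(map), path)
}

#' Build a junction marker map over fixed-width segments
#'
#' Divides each chromosome into `segment_bp`-wide segments and emits one
#' marker at every internal junction, so a chromosome of `n` segments yields
#' `n - 1` markers. Genetic positions grow linearly at `cM_per_mb` cM per Mb.
#'
#' @param chrom_lengths_bp named integer vector of chromosome lengths.
#' @param segment_bp segment width in bp (default 10 kb).
#' @param cM_per_mb genetic map expansion, cM per Mb (default 2).
#' @return [marker_map].
#' @export
make_junction_map <- function(chrom_lengths_bp, segment_bp = 10000L, cM_per_mb = 2) {
  stopifnot(!is.null(names(chrom_lengths_bp)))
  rows <- lapply(names(chrom_lengths_bp), function(ch) {
    n_seg <- ceiling(chrom_lengths_bp[[ch]] / segment_bp)
    if (n_seg < 2) return(NULL)
    pos <- segment_bp * seq_len(n_seg - 1L)
    data.frame(
      marker_id = sprintf("%s_%d", ch, pos),
      chrom = ch,
      pos_bp = as.integer(pos),
      cM = pos / 1e6 * cM_per_mb,
      stringsAsFactors = FALSE
    )
  })
  marker_map(do.call(rbind, rows))
}

#' Approximate dm3-scale chromosome arm lengths
#'
#' Chromosome arms X, 2L, 2R, 3L, 3R at roughly their dm3 sizes; chromosome 4
#' is excluded by default (too little marker information in the founder
#' panels). At 10-kb segmentation these lengths give 11,768 junction markers.
#'
#' @return named integer vector of lengths in bp.
#' @export
fly_chrom_lengths <- function() {
  c(X = 22430000L, `2L` = 23010000L, `2R` = 21150000L,
    `3L` = 24540000L, `3R` = 26600000L)
}

interp_cM <- function(map, chrom, pos_bp) {
  sub <- map[map$chrom == chrom, ]
  if (!nrow(sub)) stop_input("no markers on chrom %s", chrom)
  if (nrow(sub) == 1) return(rep(sub$cM, length(pos_bp)))
  stats::approx(sub$pos_bp, sub$cM, xout = pos_bp, rule = 2)$y
}

#' Genetic distance between a marker and a gene
#'
#' Distance in cM between a marker and a gene midpoint, used for the cis/trans
#' boundary rule. Gene genetic positions are obtained by linear interpolation
#' of the marker map along the chromosome, clamped beyond terminal markers.
#' Genes and markers on different chromosomes are infinitely distant.
#'
#' @param map [marker_map].
#' @param marker_id marker identifier present in `map`.
#' @param gene one-row data.frame (or list) with `chrom`, `start_bp`, `end_bp`.
#' @return non-negative distance in cM, or `Inf` across chromosomes.
#' @export
genetic_distance_cM <- function(map, marker_id, gene) {
  i <- match(marker_id, map$marker_id)
  if (is.na(i)) stop_input("unknown marker_id %s", marker_id)
  if (map$chrom[i] != gene$chrom) return(Inf)
  mid <- (gene$start_bp + gene$end_bp) / 2
  abs(map$cM[i] - interp_cM(map, gene$chrom, mid))
}

# Vectorized distances for hit classification: markers and genes as index
# vectors into map/annotation. Returns cM distances with Inf across chroms.
genetic_distance_many <- function(map, marker_ids, ann, gene_ids) {
  mi <- match(marker_ids, map$marker_id)
  gi <- match(gene_ids, ann$gene_id)
  if (anyNA(mi)) stop_input("unknown marker_id in distance computation")
  if (anyNA(gi)) stop_input("unknown gene_id in distance computation")
  out <- rep(Inf, length(mi))
  same <- map$chrom[mi] == ann$chrom[gi]
  if (any(same)) {
    mids <- (ann$start_bp[gi[same]] + ann$end_bp[gi[same]]) / 2
    chs <- map$chrom[mi[same]]
    gcm <- numeric(sum(same))
    for (ch in unique(chs)) {
      sel <- chs == ch
      gcm[sel] <- interp_cM(map, ch, mids[sel])
    }
    out[same] <- abs(map$cM[mi[same]] - gcm)
  }
  out
}

#' Construct a gene annotation table
#'
#' @param df data.frame with `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand` (one of `+`, `-`, `.`).
#' @return `gene_annotation` data.frame; 1-based inclusive coordinates.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start_bp", "end_bp", "strand")
  if (!all(need %in% names(df))) {
    stop_input("gene annotation needs columns: %s", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  df$start_bp <- as.integer(df$start_bp)
  df$end_bp <- as.integer(df$end_bp)
  df$strand <- as.character(df$strand)
  if (anyDuplicated(df$gene_id)) stop_input("duplicated gene_id in annotation")
  if (any(df$start_bp > df$end_bp)) stop_input("start_bp > end_bp in annotation")
  if (!all(df$strand %in% c("+", "-", "."))) stop_input("bad strand value")
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read / write gene annotation TSV
#' @param path file path.
#' @return [gene_annotation].
#' @export
read_gene_annotation <- function(path) gene_annotation(read_tsv_raw(path))

#' @rdname read_gene_annotation
#' @param ann a [gene_annotation].
#' @export
write_gene_annotation <- function(ann, path) write_tsv_exact(as.data.frame(ann), path)

#' Convert GFF3 gene lines to a gene annotation table
#'
#' Imports a GFF3 file and keeps `gene` features; the `ID` (or `gene_id`)
#' attribute becomes the gene identifier.
#'
#' @param path GFF3 file path.
#' @return [gene_annotation].
#' @export
gff3_to_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_input("gff3_to_annotation requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- gr$ID
  if (is.null(ids) && !is.null(gr$gene_id)) ids <- gr$gene_id
  gene_annotation(data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  ))
}
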