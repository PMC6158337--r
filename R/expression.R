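#' Construct an expression matrix with sample metadata
#'
#' Genes x samples abundance values (log scale after normalization), where
#' each sample is one (RIL, condition) pair and conditions are the two arms
#' of a paired design (`ctrl` / `trt`).
#'
#' @param values numeric matrix, rows = genes, columns = samples; column
#'   names follow `<ril_id>__<condition>`.
#' @return an `expression_matrix`: list with `values` and a `samples`
#'   data.frame (`sample_id`, `ril_id`, `condition`).
#' @export
expression_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression matrix needs gene and sample names")
  }
  if (anyNA(values)) stop_input("expression matrix contains missing values")
  if (anyDuplicated(colnames(values))) stop_input("duplicated sample column")
  if (anyDuplicated(rownames(values))) stop_input("duplicated gene_id")
  parts <- strsplit(colnames(values), "__", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop_input("sample columns must be named <ril_id>__<condition>")
  }
  ril <- vapply(parts, `[`, "", 1)
  cond <- vapply(parts, `[`, "", 2)
  if (!all(cond %in% c("ctrl", "trt"))) {
    stop_input("unknown condition token '%s' (expected ctrl/trt)",
               setdiff(cond, c("ctrl", "trt"))[1])
  }
  samples <- data.frame(sample_id = colnames(values), ril_id = ril,
                        condition = cond, stringsAsFactors = FALSE)
  structure(list(values = values, samples = samples), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d ctrl, %d trt)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$condition == "ctrl"),
              sum(x$samples$condition == "trt")))
  invisible(x)
}

#' Read / write an expression matrix TSV
#'
#' Dialect: first column `gene_id`, remaining columns `<ril_id>__<condition>`
#' with condition `ctrl` or `trt`; values at 9 significant digits.
#'
#' @param path file path.
#' @return [expression_matrix].
#' @export
read_expression <- function(path) {
  df <- read_tsv_raw(path)
  if (names(df)[1] != "gene_id") stop_input("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  expression_matrix(m)
}

#' @rdname read_expression
#' @param x [expression_matrix].
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values)
  names(vals) <- colnames(x$values)
  write_tsv_exact(cbind(df, vals), path)
}

#' Paired study design from sample metadata
#'
#' @param x [expression_matrix].
#' @return a `study_design` data.frame with one row per RIL: `ril_id`,
#'   `ctrl_sample`, `trt_sample`, `paired` (FALSE when one arm is absent).
#' @export
study_design <- function(x) {
  s <- x$samples
  dup <- duplicated(s[, c("ril_id", "condition")])
  if (any(dup)) stop_input("RIL %s has duplicate %s samples",
                           s$ril_id[dup][1], s$condition[dup][1])
  rils <- unique(s$ril_id)
  ctrl <- s$sample_id[match(paste0(rils, "|ctrl"), paste(s$ril_id, s$condition, sep = "|"))]
  trt <- s$sample_id[match(paste0(rils, "|trt"), paste(s$ril_id, s$condition, sep = "|"))]
  d <- data.frame(ril_id = rils, ctrl_sample = ctrl, trt_sample = trt,
                  paired = !is.na(ctrl) & !is.na(trt), stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' Extract one condition's genes x RILs matrix
#'
#' @param x [expression_matrix].
#' @param condition `"ctrl"` or `"trt"`.
#' @param rils optional RIL ordering for the columns.
#' @return numeric matrix, genes x RILs, columns named by RIL.
#' @export
condition_matrix <- function(x, condition, rils = NULL) {
  s <- x$samples
  sel <- s$condition == condition
  m <- x$values[, sel, drop = FALSE]
  colnames(m) <- s$ril_id[sel]
  if (!is.null(rils)) {
    if (!all(rils %in% colnames(m))) {
      stop_input("RILs missing from %s samples: %s", condition,
                 paste(utils::head(setdiff(rils, colnames(m)), 3), collapse = ", "))
    }
    m <- m[, rils, drop = FALSE]
  }
  m
}
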