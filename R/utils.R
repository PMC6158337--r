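#' @keywords internal
"_PACKAGE"

utils::globalVariables(c("marker_mb", "gene_mb", "specificity",
                         "marker_offset_bp", "gene_offset_bp"))

# Numbers are written with 9 significant digits everywhere so that every
# writer/reader pair round-trips exactly at that precision and repeated runs
# are byte-identical.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.9g", x))
  out
}

write_tsv_exact <- function(df, path) {
  stopifnot(is.data.frame(df))
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col)
    else if (is.logical(col)) ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    else ifelse(is.na(col), "NA", as.character(col))
  })
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(cols, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", comment.char = "")
}

# Deterministic per-stage seed derivation from one master seed: keeps every
# stochastic stage on its own reproducible stream while staying below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
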