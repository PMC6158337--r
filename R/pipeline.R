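default_pipeline_config <- function() {
  list(scenario = "mixed", seed = 1L, n_perm = 1000L, alpha = 0.05,
       cis_cm = 1.0, distant_cm = 1.0, merge_window_cm = 5.0,
       merge_lod = 1.5, hotspot_alpha = 0.05, sva_k = "auto",
       skip = character(0), out = "results")
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; `skip` takes a
#' comma-separated stage list. Unknown keys are rejected.
#'
#' @param path file path.
#' @return configuration list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  cfg <- default_pipeline_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop_input("bad config line: %s", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop_input("unknown config key: %s", key)
    cfg[[key]] <- switch(key,
      scenario = , out = val,
      sva_k = if (val == "auto") "auto" else as.integer(val),
      skip = trimws(strsplit(val, ",")[[1]]),
      seed = , n_perm = as.integer(val),
      as.numeric(val))
  }
  cfg
}

pipeline_log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full eQTL analysis pipeline on a simulated scenario
#'
#' Executes simulate -> normalize -> differential expression -> LOD scans
#' (both conditions) -> cis/trans classification and condition specificity ->
#' trans-hotspot detection -> surrogate-variable G-by-E scan -> eQTL map
#' report, writing every intermediate table as TSV under `config$out`.
#' Re-running with the same configuration and seed reproduces every output
#' byte for byte.
#'
#' @param config configuration list (see [read_pipeline_config]) or a path
#'   to a key=value config file. `skip` may name stages (`"de"`, `"gxe"`,
#'   `"hotspot"`, `"report"`) to omit.
#' @return invisibly, named vector of written file paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out <- cfg$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_con <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(log_con))
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out, paste0(name, ".tsv"))
    write_tsv_exact(df, p)
    paths[[name]] <<- p
    p
  }
  t0 <- Sys.time()
  step <- function(name, expr) {
    pipeline_log(log_con, "stage %s (seed %d)", name,
                 derive_seed(cfg$seed, name))
    tryCatch(expr, error = function(e) {
      pipeline_log(log_con, "stage %s FAILED: %s", name, conditionMessage(e))
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  sim <- step("simulate", simulate_scenario(cfg$scenario, cfg$seed))
  emit(as.data.frame(sim$map), "marker_map")
  emit(as.data.frame(sim$annotation), "annotation")
  write_truth_table(sim$truth, file.path(out, "truth.tsv"))
  paths[["truth"]] <- file.path(out, "truth.tsv")

  xn <- step("normalize", quantile_normalize_two_pass(sim$expression))
  write_expression(xn, file.path(out, "expression_normalized.tsv"))
  paths[["expression_normalized"]] <- file.path(out, "expression_normalized.tsv")

  if (!"de" %in% cfg$skip) {
    de <- step("de", differential_expression_paired(xn, sim$design))
    emit(de, "differential_expression")
  }

  scans <- list()
  hits <- list()
  for (cond in c("ctrl", "trt")) {
    nm <- paste0("scan_", cond)
    scans[[cond]] <- step(nm, scan_condition(
      xn, sim$genotypes, cond, n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, nm)))
    h <- significant_hits(scans[[cond]], cfg$alpha)
    hits[[cond]] <- classify_cis_trans(h, sim$annotation, sim$map, cfg$cis_cm)
    emit(hits[[cond]], paste0("hits_", cond))
  }

  spec_tab <- step("specificity", condition_specificity(hits$ctrl, hits$trt))
  emit(spec_tab, "specificity")

  if (!"hotspot" %in% cfg$skip) {
    hs <- list()
    for (cond in c("ctrl", "trt")) {
      nm <- paste0("hotspot_", cond)
      hs[[cond]] <- step(nm, detect_hotspots(
        scans[[cond]], sim$annotation, sim$genotypes, xn,
        alpha = cfg$alpha, distant_cM = cfg$distant_cm,
        n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, nm),
        window_cM = cfg$merge_window_cm, merge_lod = cfg$merge_lod,
        hotspot_alpha = cfg$hotspot_alpha))
      emit(data.frame(marker_id = names(hs[[cond]]$counts),
                      count = as.integer(hs[[cond]]$counts),
                      p = unname(hs[[cond]]$pvalues),
                      stringsAsFactors = FALSE),
           paste0("band_counts_", cond))
    }
    emit(compare_hotspots(hs$ctrl$hotspots, hs$trt$hotspots), "hotspots")
  }

  if (!"gxe" %in% cfg$skip) {
    sv <- step("sva", estimate_surrogates(
      xn, sim$design, k = cfg$sva_k, seed = derive_seed(cfg$seed, "sva")))
    gx <- step("gxe", gxe_scan(
      xn, sim$genotypes, sim$design, S = sv, n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, "gxe")))
    top <- apply(gx$lod, 2, which.max)
    emit(data.frame(gene_id = colnames(gx$lod),
                    marker_id = rownames(gx$lod)[top],
                    lod = gx$lod[cbind(top, seq_along(top))],
                    p = gx$p[cbind(top, seq_along(top))],
                    stringsAsFactors = FALSE),
         "gxe_top")
  }

  if (!"report" %in% cfg$skip) {
    step("report", eqtl_map_export(hits$ctrl, hits$trt, sim$map,
                                   sim$annotation,
                                   path = file.path(out, "eqtl_map.tsv")))
    paths[["eqtl_map"]] <- file.path(out, "eqtl_map.tsv")
  }
  pipeline_log(log_con, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(paths)
}
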