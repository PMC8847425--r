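config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("mp_config_error", "error")))
}
data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("mp_data_error", "error")))
}

default_config <- function() {
  list(conditions = c("reference", "disease", "rescue"),
       mode = "methylation", bin_size = 200,
       window = list(upstream = 5000, downstream = 1000),
       params = list(alpha = 0.05, fc_min = 1.5, consistency_alpha = 0.05,
                     pseudocount = 0.25, min_bins = 4),
       seed = 1, out_dir = "markpatterns_out")
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else {
      override[[k]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' YAML config with defaults filled in: `conditions` (3, reference
#' first), `mode` (`methylation` = -5 kb/+1 kb gene-body-flanked window;
#' `acetylation` = upstream -5 kb only), `bin_size`, `window`, `params`
#' (see [call_parameters()]), `seed`, `out_dir`, input paths
#' (`chrom_sizes`, `genes`, `peaks`, `gene_sets`, `enhancer_map`,
#' `pattern_table`, per-condition `tracks: {chip:, input:}`), and a
#' `simulate` block of [simulation_config()] overrides.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error("config file not found: ", path)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) config_error("bad YAML: ",
                                                      conditionMessage(e)))
    cfg <- merge_config(cfg, user)
  }
  cfg <- merge_config(cfg, overrides)
  if (length(cfg$conditions) != 3) {
    config_error("conditions must list exactly 3 entries")
  }
  if (!cfg$mode %in% c("methylation", "acetylation")) {
    config_error("mode must be 'methylation' or 'acetylation'")
  }
  bad <- tryCatch({
    do.call(call_parameters, cfg$params); NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(bad)) config_error("invalid params: ", bad)
  if (!isTRUE(cfg$bin_size > 0)) config_error("bin_size must be > 0")
  structure(cfg, class = "pipeline_config")
}

config_window_spec <- function(cfg) {
  if (cfg$mode == "acetylation") {
    window_spec(cfg$window$upstream, 0, mode = "upstream_only")
  } else {
    window_spec(cfg$window$upstream, cfg$window$downstream)
  }
}

require_paths <- function(cfg, keys) {
  for (k in keys) {
    if (is.null(cfg[[k]])) config_error("config key '", k, "' is required")
    if (!file.exists(cfg[[k]])) {
      config_error("path for '", k, "' does not exist: ", cfg[[k]])
    }
  }
}

require_tracks <- function(cfg) {
  if (is.null(cfg$tracks)) config_error("config key 'tracks' is required")
  for (cond in cfg$conditions) {
    for (ch in c("chip", "input")) {
      p <- cfg$tracks[[cond]][[ch]]
      if (is.null(p)) {
        config_error("tracks.", cond, ".", ch, " is required")
      }
      if (!file.exists(p)) {
        config_error("track file does not exist: ", p)
      }
    }
  }
}

load_tracks <- function(cfg, chrom_sizes) {
  tracks <- list()
  for (cond in cfg$conditions) {
    for (ch in c("chip", "input")) {
      tracks[[cond]][[ch]] <- tryCatch(
        read_bedgraph_track(cfg$tracks[[cond]][[ch]], cfg$bin_size,
                            chrom_sizes, label = paste0(cond, ".", ch)),
        error = function(e) data_error(conditionMessage(e)))
    }
  }
  tracks
}

write_run_metadata <- function(cfg, out_dir, log_lines) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  writeLines(c(log_lines,
               paste0("config_md5: ", unname(tools::md5sum(cfg_path)))),
             file.path(out_dir, "run.log"))
  invisible(cfg_path)
}

#' Run the `simulate` pipeline step
#'
#' Generates the synthetic dataset described by the config's `simulate`
#' block (seeded by the config seed) into `out_dir`, along with a
#' resolved-config copy and a manifest hash in the run log.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @return The [simulate_dataset()] result, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  sc <- tryCatch(do.call(simulation_config, sim_args),
                 error = function(e) config_error("invalid simulate block: ",
                                                  conditionMessage(e)))
  ds <- simulate_dataset(sc, out_dir = config$out_dir)
  write_run_metadata(config, config$out_dir,
                     c("command: simulate",
                       paste0("files: ", length(ds$files))))
  invisible(ds)
}

#' Run the `call` pipeline step
#'
#' Reads the six bedGraph tracks, genes (and peaks, if configured),
#' calls gene patterns (and peak patterns), and writes per-unit and
#' summary TSVs plus a log of skipped units.
#'
#' @param config A `pipeline_config`.
#' @return List with `gene_patterns`, `gene_summary` and, when peaks are
#'   configured, `peak_patterns`, `peak_summary`; invisibly.
#' @export
run_call <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  require_paths(config, c("chrom_sizes", "genes"))
  require_tracks(config)
  if (!is.null(config$peaks) && !file.exists(config$peaks)) {
    config_error("path for 'peaks' does not exist: ", config$peaks)
  }
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  tracks <- load_tracks(config, chrom_sizes)
  genes <- tryCatch(read_gene_annotation(config$genes),
                    error = function(e) data_error(conditionMessage(e)))
  spec <- config_window_spec(config)
  params <- do.call(call_parameters, config$params)
  gp <- call_gene_patterns(tracks, genes, spec, params)
  out <- list(gene_patterns = gp, gene_summary = summarize_patterns(gp))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_table(as.data.frame(gp), file.path(config$out_dir,
                                           "gene_patterns.tsv"))
  write_table(out$gene_summary, file.path(config$out_dir,
                                          "gene_summary.tsv"))
  log_lines <- c("command: call",
                 paste0("genes_called: ", nrow(gp)),
                 paste0("genes_skipped: ", length(attr(gp, "skipped"))))
  if (length(attr(gp, "skipped"))) {
    log_lines <- c(log_lines,
                   paste0("skipped: ", attr(gp, "skipped")))
  }
  if (!is.null(config$peaks)) {
    peaks <- tryCatch(read_bed(config$peaks),
                      error = function(e) data_error(conditionMessage(e)))
    pp <- call_peak_patterns(tracks, peaks, params)
    out$peak_patterns <- pp
    out$peak_summary <- summarize_patterns(pp)
    write_table(as.data.frame(pp), file.path(config$out_dir,
                                             "peak_patterns.tsv"))
    write_table(out$peak_summary, file.path(config$out_dir,
                                            "peak_summary.tsv"))
    log_lines <- c(log_lines, paste0("peaks_called: ", nrow(pp)))
  }
  write_run_metadata(config, config$out_dir, log_lines)
  invisible(out)
}

#' Run the `enrich` pipeline step
#'
#' Reads a per-unit pattern table (config `pattern_table`, e.g. the
#' `gene_patterns.tsv` that [run_call()] wrote) and a GMT file, and
#' writes the sorted binomial enrichment table.
#'
#' @param config A `pipeline_config`.
#' @return The enrichment data.frame, invisibly.
#' @export
run_enrich <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  require_paths(config, c("pattern_table", "gene_sets"))
  assignments <- tryCatch(
    utils::read.delim(config$pattern_table, stringsAsFactors = FALSE),
    error = function(e) data_error(conditionMessage(e)))
  if (!all(c("unit_id", "class") %in% names(assignments))) {
    data_error("pattern table lacks unit_id/class columns")
  }
  if (nrow(assignments) == 0) data_error("empty pattern table")
  sets <- tryCatch(read_gmt(config$gene_sets),
                   error = function(e) data_error(conditionMessage(e)))
  prefix <- if (any(grepl("^PP", assignments$class))) "PP" else "GP"
  res <- enrich_gene_sets(assignments, sets,
                          patterns = paste0(prefix, 1:4))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_table(res, file.path(config$out_dir, "enrichment.tsv"))
  write_run_metadata(config, config$out_dir,
                     c("command: enrich",
                       paste0("results: ", nrow(res))))
  invisible(res)
}

#' Run the `compare` pipeline step
#'
#' Genome-wide per-gene fold-change table per condition plus the
#' pairwise two-sided Mann-Whitney p-value matrix between conditions
#' (diagonal 1), written as TSVs.
#'
#' @param config A `pipeline_config`.
#' @return List with `fc_table` and `p_matrix`, invisibly.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  require_paths(config, c("chrom_sizes", "genes"))
  require_tracks(config)
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  tracks <- load_tracks(config, chrom_sizes)
  genes <- tryCatch(read_gene_annotation(config$genes),
                    error = function(e) data_error(conditionMessage(e)))
  fc <- genomewide_fc_table(tracks, genes, config_window_spec(config),
                            do.call(call_parameters, config$params))
  conds <- config$conditions
  pm <- matrix(1, 3, 3, dimnames = list(conds, conds))
  for (i in 1:2) for (j in (i + 1):3) {
    p <- compare_fc_distributions(fc[[paste0("fc_", conds[i])]],
                                  fc[[paste0("fc_", conds[j])]])
    pm[i, j] <- pm[j, i] <- p
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_table(fc, file.path(config$out_dir, "fc_table.tsv"))
  write_table(cbind(data.frame(condition = conds), as.data.frame(pm)),
              file.path(config$out_dir, "fc_comparison.tsv"))
  write_run_metadata(config, config$out_dir,
                     c("command: compare",
                       paste0("genes: ", nrow(fc))))
  invisible(list(fc_table = fc, p_matrix = pm))
}

#' Run the `summarize` pipeline step
#'
#' Re-summarizes an existing per-unit pattern TSV into class counts and
#' percentages.
#'
#' @param config A `pipeline_config` with `pattern_table` set.
#' @return The summary data.frame, invisibly.
#' @export
run_summarize <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  require_paths(config, "pattern_table")
  assignments <- utils::read.delim(config$pattern_table,
                                   stringsAsFactors = FALSE)
  if (!all(c("unit_id", "class") %in% names(assignments))) {
    data_error("pattern table lacks unit_id/class columns")
  }
  s <- summarize_patterns(assignments)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write_table(s, file.path(config$out_dir, "pattern_summary.tsv"))
  write_run_metadata(config, config$out_dir, "command: summarize")
  invisible(s)
}
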