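STATIC_CODES <- c("UUU", "III", "IIU", "UUI")

#' Configuration for the synthetic coverage simulator
#'
#' Defines the three-condition (reference / disease / rescue) study the
#' simulator emulates: negative-binomial bin counts for ChIP and Input
#' channels, genes placed so that their quantification windows are
#' disjoint, and per-gene planted I/U codes with a planted fold-change
#' applied to the ChIP mean wherever the state is I.
#'
#' Defaults: 200 genes of 2-4 kb on one 4 Mb chromosome, 200 bp bins
#' (so a -5 kb/+1 kb window holds 40-50 bins), planted fold-change 3
#' (log2 1.585, sd 0), Input mean 10 counts/bin, NB dispersion 0.1,
#' class mix 20% each of GP1-GP4 and static.
#'
#' @param seed Integer RNG seed; the whole dataset is deterministic in it.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Number of genes to place.
#' @param gene_length Length-2 vector, min/max gene length in bp.
#' @param bin_size Bin width in bp.
#' @param conditions Condition labels, length 3, reference first.
#' @param class_props Named proportions over GP1-GP4 and static; must sum
#'   to 1.
#' @param log2fc_mean,log2fc_sd Planted log2 fold-change distribution for
#'   I states.
#' @param input_depth Mean Input counts per bin.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param gap Extra bp between consecutive gene envelopes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_chroms = 1, chrom_length = 4e6,
                              n_genes = 200,
                              gene_length = c(2000, 4000), bin_size = 200,
                              conditions = c("reference", "disease", "rescue"),
                              class_props = c(GP1 = 0.2, GP2 = 0.2,
                                              GP3 = 0.2, GP4 = 0.2,
                                              static = 0.2),
                              log2fc_mean = log2(3), log2fc_sd = 0,
                              input_depth = 10, dispersion = 0.1,
                              gap = 400) {
  stopifnot(length(conditions) == 3, input_depth > 0, dispersion > 0,
            n_genes >= 1, bin_size > 0, length(gene_length) == 2,
            gene_length[1] <= gene_length[2], gene_length[1] >= 1)
  if (abs(sum(class_props) - 1) > 1e-8) stop("class_props must sum to 1")
  if (!all(names(class_props) %in% PATTERN_CLASSES)) {
    stop("class_props names must be GP1..GP4/static")
  }
  structure(list(seed = seed, n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 gene_length = gene_length, bin_size = bin_size,
                 conditions = conditions, class_props = class_props,
                 log2fc_mean = log2fc_mean, log2fc_sd = log2fc_sd,
                 input_depth = input_depth, dispersion = dispersion,
                 gap = gap, window_margin = 5000, window_down = 1000),
            class = "simulation_config")
}

#' Simulate a gene annotation with disjoint quantification windows
#'
#' Genes are packed left to right with an envelope wide enough that the
#' default -5 kb/+1 kb windows of distinct genes never overlap on either
#' strand, so planted truth is unambiguous. Strand is uniform.
#'
#' @param config A [simulation_config()].
#' @return List with `genes` (stranded interval data.frame with
#'   `gene_id`) and `chrom_sizes`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  M <- config$window_margin
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms), chroms)
  rows <- list()
  g <- 1
  for (chr in chroms) {
    pos <- M
    while (g <= config$n_genes) {
      L <- sample(config$gene_length[1]:config$gene_length[2], 1)
      if (pos + L + M + config$window_down > config$chrom_length) break
      rows[[g]] <- data.frame(
        chrom = chr, start = pos, end = pos + L,
        name = sprintf("gene_%03d", g),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      pos <- pos + L + 2 * M + config$window_down + config$gap
      g <- g + 1
    }
    if (g > config$n_genes) break
  }
  if (g <= config$n_genes) {
    stop("infeasible packing: cannot place ", config$n_genes,
         " genes; increase chrom_length or n_chroms")
  }
  genes <- validate_intervals(do.call(rbind, rows), require_strand = TRUE)
  genes$gene_id <- genes$name
  list(genes = genes, chrom_sizes = chrom_sizes)
}

#' Plant per-gene pattern truth
#'
#' Assigns each gene a class by the configured proportions (dynamic
#' classes get their defining code; static genes draw uniformly from the
#' four static codes) and a planted fold-change applied in every
#' condition whose state is I.
#'
#' @param config A [simulation_config()].
#' @param genes Annotation from [simulate_annotation()].
#' @return Truth data.frame: `gene_id`, `code`, `class`, and one
#'   `fc_<condition>` column per condition.
#' @export
plant_truth <- function(config, genes) {
  set.seed(config$seed + 1L)
  n <- nrow(genes)
  counts <- diff(c(0, round(cumsum(config$class_props) * n)))
  classes <- sample(rep(names(config$class_props), counts))
  code_of <- setNames(DYNAMIC_CODES, c("GP1", "GP2", "GP3", "GP4"))
  codes <- ifelse(classes == "static",
                  sample(STATIC_CODES, n, replace = TRUE),
                  code_of[classes])
  fc <- 2 ^ stats::rnorm(n, config$log2fc_mean, config$log2fc_sd)
  truth <- data.frame(gene_id = genes$gene_id, code = unname(codes),
                      class = classes, stringsAsFactors = FALSE)
  for (j in seq_along(config$conditions)) {
    state <- substr(truth$code, j, j)
    truth[[paste0("fc_", config$conditions[j])]] <- ifelse(state == "I", fc, 1)
  }
  truth
}

#' Simulate ChIP and Input coverage tracks with planted signal
#'
#' Every bin draws negative-binomial counts. Input bins (and ChIP
#' background bins) have mean `input_depth`; inside a gene's
#' quantification window, the ChIP mean is multiplied by the gene's
#' planted fold-change in each condition whose planted state is I.
#' Deterministic given the config seed. Optionally writes the six
#' bedGraphs to `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param genes,chrom_sizes From [simulate_annotation()].
#' @param truth From [plant_truth()].
#' @param out_dir Optional directory for bedGraph output.
#' @return Named list (by condition) of `list(chip =, input =)` raw
#'   [binned_track()]s; written file paths in the `files` attribute when
#'   `out_dir` is given.
#' @export
simulate_tracks <- function(config, genes, chrom_sizes, truth,
                            out_dir = NULL) {
  if (!setequal(truth$gene_id, genes$gene_id)) {
    stop("truth does not cover the annotation")
  }
  set.seed(config$seed + 2L)
  size_nb <- 1 / config$dispersion
  spec <- window_spec(config$window_margin, config$window_down)
  windows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    gene_window(genes[i, ], spec, chrom_sizes)))
  truth <- truth[match(genes$gene_id, truth$gene_id), ]
  out <- list()
  files <- character(0)
  for (cond in config$conditions) {
    state <- substr(truth$code, match(cond, config$conditions),
                    match(cond, config$conditions))
    for (channel in c("chip", "input")) {
      bins <- list()
      for (chr in names(chrom_sizes)) {
        n_bins <- ceiling(chrom_sizes[[chr]] / config$bin_size)
        v <- stats::rnbinom(n_bins, mu = config$input_depth, size = size_nb)
        if (channel == "chip") {
          for (i in which(state == "I" & windows$chrom == chr)) {
            b0 <- floor(windows$start[i] / config$bin_size)
            b1 <- ceiling(windows$end[i] / config$bin_size) - 1
            mu <- config$input_depth * truth[[paste0("fc_", cond)]][i]
            v[(b0:b1) + 1] <- stats::rnbinom(b1 - b0 + 1, mu = mu,
                                             size = size_nb)
          }
        }
        bins[[chr]] <- as.numeric(v)
      }
      tr <- binned_track(bins, config$bin_size, chrom_sizes,
                         label = paste0(cond, ".", channel))
      out[[cond]][[channel]] <- tr
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(cond, "_", channel, ".bedGraph"))
        write_bedgraph(tr, path)
        files <- c(files, path)
      }
    }
  }
  attr(out, "files") <- files
  out
}

#' Simulate a complete synthetic dataset
#'
#' Annotation, planted truth and six coverage tracks in one call; with
#' `out_dir`, also writes `genes.bed`, `chrom.sizes`, `truth.tsv` and the
#' bedGraphs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List: `config`, `genes`, `chrom_sizes`, `truth`, `tracks`,
#'   `files`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  ann <- simulate_annotation(config)
  truth <- plant_truth(config, ann$genes)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  tracks <- simulate_tracks(config, ann$genes, ann$chrom_sizes, truth,
                            out_dir = out_dir)
  files <- attr(tracks, "files")
  if (!is.null(out_dir)) {
    write_bed(ann$genes, file.path(out_dir, "genes.bed"))
    writeLines(sprintf("%s\t%d", names(ann$chrom_sizes),
                       as.integer(ann$chrom_sizes)),
               file.path(out_dir, "chrom.sizes"))
    write_table(truth, file.path(out_dir, "truth.tsv"))
    files <- c(files, file.path(out_dir, c("genes.bed", "chrom.sizes",
                                           "truth.tsv")))
  }
  list(config = config, genes = ann$genes, chrom_sizes = ann$chrom_sizes,
       truth = truth, tracks = tracks, files = files)
}

#' Score pattern recovery against planted truth
#'
#' @param assignments A `pattern_calls` table over the simulated genes
#'   (peak-mode PP labels are mapped onto the GP classes).
#' @param truth Truth table from [plant_truth()].
#' @return List: 5x5 `confusion` matrix (truth x predicted over GP1-GP4,
#'   static), per-class `recall`, and overall `accuracy`.
#' @export
evaluate_recovery <- function(assignments, truth) {
  pred <- setNames(sub("^PP", "GP", assignments$class), assignments$unit_id)
  if (!setequal(names(pred), truth$gene_id)) {
    stop("assignment and truth gene ids do not match")
  }
  pred <- pred[truth$gene_id]
  lv <- PATTERN_CLASSES
  confusion <- table(truth = factor(truth$class, lv),
                     predicted = factor(pred, lv))
  recall <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion, recall = recall,
       accuracy = sum(diag(confusion)) / sum(confusion))
}
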