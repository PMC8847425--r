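#' Gene-proximal window specification
#'
#' The quantification window around a gene. The default
#' `gene_body_flanked` mode spans from 5 kb upstream of the 5' end to 1 kb
#' downstream of the 3' end, gene body included, which suits broad
#' repressive marks such as H3K27me3. `upstream_only` restricts to the
#' `upstream_bp` immediately 5' of the gene start (promoter/enhancer side),
#' the convention used for H3K27ac, and forces `downstream_bp = 0`.
#'
#' @param upstream_bp bp on the 5' side (default 5000).
#' @param downstream_bp bp on the 3' side (default 1000).
#' @param mode `"gene_body_flanked"` or `"upstream_only"`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(upstream_bp = 5000, downstream_bp = 1000,
                        mode = c("gene_body_flanked", "upstream_only")) {
  mode <- match.arg(mode)
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  if (mode == "upstream_only") downstream_bp <- 0
  structure(list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 mode = mode), class = "window_spec")
}

#' Compute the quantification window for one gene
#'
#' Strand-aware: on the minus strand the 5' end is the interval end, so
#' upstream flank and downstream flank swap sides. The window is clipped
#' to `[0, chrom_length)`; a window that is empty after clipping is an
#' error naming the gene.
#'
#' @param gene One-row data.frame with `chrom`, `start`, `end`, `strand`,
#'   `name` (strand must be `+` or `-`).
#' @param spec A [window_spec()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return One-row interval data.frame.
#' @export
gene_window <- function(gene, spec = window_spec(), chrom_sizes) {
  chr <- as.character(gene$chrom[1])
  if (!chr %in% names(chrom_sizes)) {
    stop("gene ", gene$name[1], ": unknown chromosome ", chr)
  }
  strand <- as.character(gene$strand[1])
  if (!strand %in% c("+", "-")) stop("gene ", gene$name[1], ": no strand")
  s <- gene$start[1]; e <- gene$end[1]
  if (spec$mode == "gene_body_flanked") {
    w <- if (strand == "+") {
      c(s - spec$upstream_bp, e + spec$downstream_bp)
    } else {
      c(s - spec$downstream_bp, e + spec$upstream_bp)
    }
  } else {  # upstream_only: the upstream_bp immediately 5' of the gene
    w <- if (strand == "+") c(s - spec$upstream_bp, s) else c(e, e + spec$upstream_bp)
  }
  w <- c(max(0, w[1]), min(chrom_sizes[[chr]], w[2]))
  if (w[1] >= w[2]) {
    stop("gene ", gene$name[1], ": window empty after clipping")
  }
  data.frame(chrom = chr, start = w[1], end = w[2],
             name = as.character(gene$name[1]), strand = strand,
             stringsAsFactors = FALSE)
}

gene_windows <- function(genes, spec, chrom_sizes) {
  # vectorized loop over rows; failures recorded, not fatal
  out <- vector("list", nrow(genes))
  skipped <- character(0)
  msgs <- character(0)
  for (i in seq_len(nrow(genes))) {
    w <- tryCatch(gene_window(genes[i, ], spec, chrom_sizes),
                  error = function(e) conditionMessage(e))
    if (is.character(w)) {
      skipped <- c(skipped, genes$name[i])
      msgs <- c(msgs, w)
    } else {
      out[[i]] <- w
    }
  }
  windows <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  list(windows = windows, skipped = skipped, messages = msgs)
}

#' Region fold-change of ChIP over Input
#'
#' Scalar fold-change is the ratio of pseudocount-adjusted mean bin
#' intensities; the per-bin vector is `log2((chip_b + pc) / (input_b + pc))`
#' and feeds the peak-level consistency filter.
#'
#' @param chip_bins,input_bins Equal-length CPM bin vectors for one region.
#' @param pseudocount Symmetric pseudocount in CPM (> 0), default 0.25.
#' @return List with `fc` (scalar) and `log2fc` (per-bin vector).
#' @export
region_fold_change <- function(chip_bins, input_bins, pseudocount = 0.25) {
  if (length(chip_bins) != length(input_bins)) {
    stop("chip and input bin vectors differ in length")
  }
  if (length(chip_bins) < 1) stop("empty region")
  if (!isTRUE(pseudocount > 0)) stop("pseudocount must be > 0")
  list(fc = (mean(chip_bins) + pseudocount) / (mean(input_bins) + pseudocount),
       log2fc = log2((chip_bins + pseudocount) / (input_bins + pseudocount)))
}

#' Assign peaks to genes by window overlap
#'
#' A (peak, gene) pair is emitted when the peak overlaps the gene's
#' quantification window by at least 1 bp; duplicate pairs are merged.
#' With an enhancer map (data.frame `chrom`, `start`, `end`, `gene_id`),
#' peaks overlapping an enhancer also pair with the enhancer's gene.
#' Peaks hitting no gene are reported with `gene_id = NA`.
#'
#' @param peaks Interval data.frame (see [read_bed()]).
#' @param genes Stranded gene data.frame (see [read_gene_annotation()]).
#' @param spec A [window_spec()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param enhancer_map Optional enhancer-to-gene data.frame.
#' @return data.frame with columns `peak_id`, `gene_id`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, spec = window_spec(),
                                  chrom_sizes, enhancer_map = NULL) {
  gw <- gene_windows(genes, spec, chrom_sizes)$windows
  pairs <- overlap_pairs(peaks, gw)
  if (!is.null(enhancer_map)) {
    stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(enhancer_map)))
    enh <- data.frame(chrom = enhancer_map$chrom, start = enhancer_map$start,
                      end = enhancer_map$end, name = enhancer_map$gene_id,
                      stringsAsFactors = FALSE)
    pairs <- rbind(pairs, overlap_pairs(peaks, enh))
  }
  pairs <- unique(pairs)
  orphan <- setdiff(peaks$name, pairs$peak_id)
  if (length(orphan)) {
    pairs <- rbind(pairs, data.frame(peak_id = orphan,
                                     gene_id = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  pairs <- pairs[order(match(pairs$peak_id, peaks$name), pairs$gene_id), ]
  rownames(pairs) <- NULL
  pairs
}

overlap_pairs <- function(peaks, targets) {
  if (is.null(targets) || nrow(targets) == 0) {
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(intersect(unique(peaks$chrom), unique(targets$chrom)),
                function(chr) {
    p <- peaks[peaks$chrom == chr, ]
    g <- targets[targets$chrom == chr, ]
    hits <- IRanges::findOverlaps(intervals_to_iranges(p),
                                  intervals_to_iranges(g))
    data.frame(peak_id = p$name[as.matrix(hits)[, 1]],
               gene_id = g$name[as.matrix(hits)[, 2]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(data.frame(peak_id = character(0),
                                        gene_id = character(0),
                                        stringsAsFactors = FALSE))))
}
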