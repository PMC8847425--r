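# In-code fixtures shared across test files.

# Single-chromosome CPM track from a plain bin vector
toy_track <- function(v, bin_size = 200, chrom = "chr1",
                      size = length(v) * bin_size, label = "",
                      normalized = TRUE) {
  binned_track(setNames(list(as.numeric(v)), chrom), bin_size,
               setNames(size, chrom), library_size = max(sum(v), 1),
               label = label, normalized = normalized)
}

# Three-condition track set with one gene at chr1:[5000,7000)+ whose
# -5kb/+1kb window is [0,8000) = bins 1..40 at 200 bp. ChIP is
# `fc` x Input inside the window in every condition whose code letter is
# I; elsewhere ChIP == Input.
planted_gene <- function() {
  data.frame(chrom = "chr1", start = 5000, end = 7000, name = "g1",
             strand = "+", gene_id = "g1", stringsAsFactors = FALSE)
}

planted_tracks <- function(code, fc = 3, seed = 42, n_bins = 65,
                           bin_size = 200, noisy = TRUE) {
  set.seed(seed)
  conds <- c("reference", "disease", "rescue")
  states <- strsplit(code, "")[[1]]
  win_bins <- 1:40
  out <- list()
  for (i in seq_along(conds)) {
    input <- if (noisy) runif(n_bins, 8, 12) else rep(10, n_bins)
    chip <- input
    if (states[i] == "I") chip[win_bins] <- input[win_bins] * fc
    out[[conds[i]]] <- list(
      chip = toy_track(chip, bin_size, label = paste0(conds[i], ".chip")),
      input = toy_track(input, bin_size, label = paste0(conds[i], ".input")))
  }
  out
}

tiny_sim_config <- function(seed = 5, n_genes = 12, chrom_length = 3e5, ...) {
  simulation_config(seed = seed, n_genes = n_genes,
                    chrom_length = chrom_length, ...)
}
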