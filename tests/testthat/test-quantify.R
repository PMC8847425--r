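test_that("CPM normalization scales by library size and is scale-invariant", {
  tr <- binned_track(list(chr1 = c(2, 0, 8)), 50, c(chr1 = 150),
                     library_size = 10)
  cpm <- normalize_cpm(tr)
  expect_equal(cpm$bins$chr1, c(2e5, 0, 8e5))
  expect_true(cpm$normalized)
  # x3 raw mass with x3 library size gives identical CPM
  tr3 <- binned_track(list(chr1 = 3 * c(2, 0, 8)), 50, c(chr1 = 150),
                      library_size = 30)
  expect_equal(normalize_cpm(tr3)$bins, cpm$bins)
  # total CPM equals 1e6 * raw mass / library size
  set.seed(3)
  v <- rpois(100, 4)
  trr <- binned_track(list(chr1 = as.numeric(v)), 10, c(chr1 = 1000),
                      library_size = 777)
  expect_equal(sum(normalize_cpm(trr)$bins$chr1), 1e6 * sum(v) / 777)
})

test_that("an all-zero track has no valid library size", {
  expect_error(binned_track(list(chr1 = c(0, 0)), 50, c(chr1 = 100)),
               "library_size")
})

test_that("gene windows are strand-aware and mode-aware", {
  sizes <- c(chr1 = 1e6)
  g <- function(strand) data.frame(chrom = "chr1", start = 10000,
                                   end = 12000, name = "g", strand = strand)
  spec <- window_spec(5000, 1000)
  wp <- gene_window(g("+"), spec, sizes)
  expect_equal(c(wp$start, wp$end), c(5000, 13000))
  wm <- gene_window(g("-"), spec, sizes)
  expect_equal(c(wm$start, wm$end), c(9000, 17000))
  up <- window_spec(5000, mode = "upstream_only")
  expect_equal(up$downstream_bp, 0)
  wu <- gene_window(g("+"), up, sizes)
  expect_equal(c(wu$start, wu$end), c(5000, 10000))
  wum <- gene_window(g("-"), up, sizes)
  expect_equal(c(wum$start, wum$end), c(12000, 17000))
})

test_that("gene windows clip to the chromosome and flag empty windows", {
  sizes <- c(chr1 = 11000)
  g <- data.frame(chrom = "chr1", start = 1000, end = 10500, name = "g",
                  strand = "+")
  w <- gene_window(g, window_spec(5000, 1000), sizes)
  expect_equal(c(w$start, w$end), c(0, 11000))
  g0 <- data.frame(chrom = "chr1", start = 0, end = 100, name = "g0",
                   strand = "+")
  expect_error(
    gene_window(g0, window_spec(5000, mode = "upstream_only"), sizes),
    "g0.*empty")
})

test_that("strand flip mirrors flank placement around the gene body", {
  sizes <- c(chr1 = 1e6)
  set.seed(11)
  spec <- window_spec(4000, 1500)
  for (i in 1:20) {
    s <- sample(20000:50000, 1); e <- s + sample(100:5000, 1)
    gp <- data.frame(chrom = "chr1", start = s, end = e, name = "g",
                     strand = "+")
    gm <- gp; gm$strand <- "-"
    wp <- gene_window(gp, spec, sizes)
    wm <- gene_window(gm, spec, sizes)
    # distances of window edges from the gene are swapped between strands
    expect_equal(s - wp$start, 4000)
    expect_equal(wp$end - e, 1500)
    expect_equal(s - wm$start, 1500)
    expect_equal(wm$end - e, 4000)
  }
})

test_that("extract_bins returns whole boundary bins in genomic order", {
  tr <- toy_track(c(1, 2, 3, 4), bin_size = 50)
  expect_equal(extract_bins(tr, list(chrom = "chr1", start = 0, end = 100)),
               c(1, 2))
  expect_equal(extract_bins(tr, list(chrom = "chr1", start = 60, end = 90)),
               2)
  expect_equal(extract_bins(tr, list(chrom = "chr1", start = 60, end = 110)),
               c(2, 3))
  expect_error(extract_bins(tr, list(chrom = "chrX", start = 0, end = 10)),
               "unknown chromosome")
})

test_that("a chromosome with no coverage yields a zero vector of full length", {
  tr <- binned_track(list(chr1 = c(1, 1)), 50, c(chr1 = 100, chr2 = 300),
                     library_size = 2)
  expect_equal(extract_bins(tr, list(chrom = "chr2", start = 0, end = 300)),
               c(0, 0, 0, 0, 0, 0))
})

test_that("region fold-change follows the pseudocount-adjusted mean ratio", {
  v <- c(1, 4, 2.5)
  r <- region_fold_change(v, v, 0.25)
  expect_equal(r$fc, 1)
  expect_equal(r$log2fc, rep(0, 3))
  r2 <- region_fold_change(c(3, 3), c(1, 1), 0.5)
  expect_equal(r2$fc, 3.5 / 1.5)
  r3 <- region_fold_change(c(0, 0), c(0, 0), 0.5)
  expect_equal(r3$fc, 1)
  expect_error(region_fold_change(1:3, 1:2), "length")
  expect_error(region_fold_change(1:3, 4:6, 0), "pseudocount")
})

test_that("peak-to-gene assignment matches a brute-force all-pairs sweep", {
  sizes <- c(chr1 = 2e5, chr2 = 2e5)
  spec <- window_spec(5000, 1000)
  set.seed(99)
  for (rep in 1:3) {
    np <- sample(30:60, 1); ng <- sample(20:40, 1)
    ps <- sample(0:190000, np)
    peaks <- validate_intervals(data.frame(
      chrom = sample(c("chr1", "chr2"), np, TRUE), start = ps,
      end = ps + sample(200:8000, np, TRUE), name = paste0("p", 1:np),
      strand = "*"))
    peaks$end <- pmin(peaks$end, 2e5)
    gs <- sample(6000:180000, ng)
    genes <- validate_intervals(data.frame(
      chrom = sample(c("chr1", "chr2"), ng, TRUE), start = gs,
      end = gs + sample(500:10000, ng, TRUE), name = paste0("g", 1:ng),
      strand = sample(c("+", "-"), ng, TRUE)), require_strand = TRUE)
    genes$end <- pmin(genes$end, 190000)
    windows <- do.call(rbind, lapply(seq_len(ng), function(i)
      gene_window(genes[i, ], spec, sizes)))
    got <- assign_peaks_to_genes(peaks, genes, spec, sizes)
    got <- got[!is.na(got$gene_id), ]
    want <- brute_force_pairs(peaks, windows)
    key <- function(d) sort(paste(d$peak_id, d$gene_id))
    expect_equal(key(got), key(want))
  }
})

test_that("assignment emits overlaps, orphans and enhancer-mapped pairs", {
  sizes <- c(chr1 = 1e5)
  genes <- data.frame(chrom = "chr1", start = 10000, end = 12000,
                      name = "g1", strand = "+")
  peaks <- validate_intervals(data.frame(
    chrom = "chr1", start = c(4000, 0, 40000),
    end = c(6000, 1000, 41000), name = c("pkA", "pkB", "pkC"),
    strand = "*"))
  got <- assign_peaks_to_genes(peaks, genes, window_spec(5000, 1000), sizes)
  expect_equal(got$gene_id[got$peak_id == "pkA"], "g1")
  expect_true(is.na(got$gene_id[got$peak_id == "pkB"]))
  enh <- data.frame(chrom = "chr1", start = 40500, end = 40800,
                    gene_id = "g1")
  got2 <- assign_peaks_to_genes(peaks, genes, window_spec(5000, 1000),
                                sizes, enhancer_map = enh)
  expect_equal(got2$gene_id[got2$peak_id == "pkC"], "g1")
})
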