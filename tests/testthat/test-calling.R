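test_that("I/U designation is the strict conjunction of p and fold-change", {
  params <- call_parameters()
  v <- runif(20, 8, 12)
  expect_equal(iu_call(v, v, params)$designation, "U")     # fc = 1
  # complete separation but fold-change pinned at 1.4: never I
  set.seed(31)
  input <- runif(40, 9.5, 10.5)
  target <- 1.4 * (mean(input) + params$pseudocount) - params$pseudocount
  chip <- runif(40, 13, 15)
  chip <- chip * target / mean(chip)
  call <- iu_call(chip, input, params)
  expect_lt(call$p_value, 0.05)
  expect_equal(call$fold_change, 1.4, tolerance = 1e-12)
  expect_equal(call$designation, "U")
  # strong enrichment: both thresholds met
  set.seed(32)
  input2 <- runif(20, 8, 12)
  chip2 <- input2 * 3 + rnorm(20, 0, 0.5)
  call2 <- iu_call(chip2, input2, params)
  expect_equal(call2$designation, "I")
  expect_equal(call2$p_value, mann_whitney_one_sided(chip2, input2))
  expect_equal(call2$fold_change,
               region_fold_change(chip2, input2, params$pseudocount)$fc)
})

test_that("designation equals (p < alpha AND fc > fc_min) on random regions", {
  set.seed(33)
  params <- call_parameters()
  for (i in 1:200) {
    n <- sample(4:30, 1)
    input <- runif(n, 0, 20)
    chip <- runif(n, 0, 20) * sample(c(0.5, 1, 1.4, 1.6, 3), 1)
    call <- iu_call(chip, input, params)
    expect_identical(call$designation,
                     if (call$p_value < params$alpha &&
                         call$fold_change > params$fc_min) "I" else "U")
  }
})

test_that("regions with too few bins are called U with a low-coverage flag", {
  call <- iu_call(c(100, 100, 100), c(1, 1, 1), call_parameters())
  expect_equal(call$designation, "U")
  expect_true(call$low_coverage)
  expect_true(is.na(call$p_value))
})

test_that("the 8 codes map to 4 dynamic classes bijectively, rest static", {
  codes <- apply(expand.grid(c("I", "U"), c("I", "U"), c("I", "U")), 1,
                 paste, collapse = "")
  labels <- vapply(codes, classify_code, "", unit_kind = "gene")
  expect_equal(labels[["IUI"]], "GP1")
  expect_equal(labels[["IUU"]], "GP2")
  expect_equal(labels[["UII"]], "GP3")
  expect_equal(labels[["UIU"]], "GP4")
  expect_equal(sum(labels == "static"), 4)
  dyn <- labels[labels != "static"]
  expect_equal(sort(unname(dyn)), paste0("GP", 1:4))  # bijection
  expect_equal(classify_code("UIU", "peak"), "PP4")
  expect_error(classify_code("IU", "gene"), "length-3")
  expect_error(classify_code("IUX", "gene"), "length-3|\\{I, U\\}")
})

test_that("consistency filter demands I fold-changes dominate U fold-changes", {
  # all-I: vacuous pass
  fcs <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_true(consistency_filter(fcs, "III"))
  # identical fold-change distributions cannot pass
  v <- c(0.2, -0.1, 0.5, 0.3, -0.4, 0.1)
  expect_false(consistency_filter(list(v, v, v), "IUU"))
  # planted separation: I conditions near +1.5 log2, U near 0
  set.seed(34)
  sep <- list(r = rnorm(30, 1.5, 0.3), d = rnorm(30, 0, 0.3),
              x = rnorm(30, 1.5, 0.3))
  expect_true(consistency_filter(sep, "IUI"))
  expect_error(consistency_filter(list(1:3, 1:4, 1:3), "IUI"), "length")
})

test_that("tightening consistency_alpha never promotes a unit to dynamic", {
  set.seed(35)
  for (i in 1:50) {
    shift <- runif(1, 0, 1.5)
    fcs <- list(rnorm(15, shift), rnorm(15), rnorm(15, shift))
    for (alphas in list(c(0.05, 0.01), c(0.01, 0.001))) {
      hi <- consistency_filter(fcs, "IUI", alphas[1])
      lo <- consistency_filter(fcs, "IUI", alphas[2])
      expect_false(lo && !hi)
    }
  }
})

test_that("gene patterns: identical tracks are static, planted codes recover", {
  gene <- planted_gene()
  quiet <- planted_tracks("UUU")
  gp0 <- call_gene_patterns(quiet, gene)
  expect_equal(gp0$code, "UUU")
  expect_equal(gp0$class, "static")
  expect_true(is.na(gp0$consistency_pass))
  for (planted in c("IUI", "IUU", "UII", "UIU")) {
    gp <- call_gene_patterns(planted_tracks(planted), gene)
    expect_equal(gp$code, planted)
    expect_equal(gp$class,
                 paste0("GP", match(planted, c("IUI", "IUU", "UII", "UIU"))))
  }
})

test_that("genes with invalid windows are skipped, not fatal", {
  tracks <- planted_tracks("UUU")
  genes <- rbind(planted_gene(),
                 data.frame(chrom = "chr1", start = 0, end = 100,
                            name = "g_edge", strand = "+",
                            gene_id = "g_edge"))
  gp <- call_gene_patterns(tracks, genes,
                           window_spec(5000, mode = "upstream_only"))
  expect_equal(gp$unit_id, "g1")
  expect_equal(attr(gp, "skipped"), "g_edge")
})

test_that("peak patterns apply the consistency filter with demotion", {
  peak <- data.frame(chrom = "chr1", start = 0, end = 8000, name = "pk1",
                     strand = "*")
  pp <- call_peak_patterns(planted_tracks("IUI"), peak)
  expect_equal(pp$class, "PP1")
  expect_true(pp$consistency_pass)
  # Increased call driven by a subset of elevated bins, while a U library
  # carries a uniform sub-threshold shift: the per-bin fold-change of the
  # I library does not dominate it, so the dynamic code is demoted
  mkt <- function(v) toy_track(v, 200)
  input <- rep(10, 65)
  chip_ref <- input; chip_ref[1:40] <- rep(c(24, 10), 20)
  chip_dis <- input; chip_dis[1:40] <- 13
  tracks <- list(reference = list(chip = mkt(chip_ref), input = mkt(input)),
                 disease = list(chip = mkt(chip_dis), input = mkt(input)),
                 rescue = list(chip = mkt(input), input = mkt(input)))
  pp2 <- call_peak_patterns(tracks, peak)
  expect_equal(pp2$code, "IUU")
  expect_equal(pp2$class, "static")
  expect_false(pp2$consistency_pass)
  # without the filter the same peak keeps its dynamic class
  pp2b <- call_peak_patterns(tracks, peak, consistency = FALSE)
  expect_equal(pp2b$class, "PP2")
  # zero-signal peak
  pp3 <- call_peak_patterns(planted_tracks("UUU"), peak)
  expect_equal(pp3$code, "UUU")
  expect_equal(pp3$class, "static")
})

test_that("pattern summaries count and percentage dynamic classes", {
  expect_equal(summarize_patterns(c(GP1 = 1))$percent, c(100, 100))
  s2 <- summarize_patterns(c(GP1 = 1, GP4 = 1))
  expect_equal(s2$percent, c(50, 50, 100))
  df <- data.frame(unit_id = letters[1:5],
                   class = c("GP1", "GP1", "GP2", "static", "static"))
  s3 <- summarize_patterns(df)
  expect_equal(s3$count[s3$class == "total"], 3)
  expect_equal(s3$percent[s3$class == "GP1"], 67)
  expect_warning(s0 <- summarize_patterns(c(static = 10)), "no dynamic")
  expect_equal(nrow(s0), 0)
})

test_that("genome-wide fold-change table covers every callable gene", {
  gene <- planted_gene()
  fc0 <- genomewide_fc_table(planted_tracks("UUU"), gene)
  expect_equal(unname(unlist(fc0[1, -1])), rep(1, 3), tolerance = 1e-12)
  tr <- planted_tracks("III", fc = 2, noisy = FALSE)
  fc2 <- genomewide_fc_table(tr, gene)
  expect_equal(fc2$fc_reference, (20 + 0.25) / (10 + 0.25))
  genes2 <- rbind(gene, data.frame(chrom = "chr1", start = 9000, end = 9500,
                                   name = "g2", strand = "-",
                                   gene_id = "g2"))
  expect_equal(nrow(genomewide_fc_table(planted_tracks("UUU"), genes2)), 2)
})
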