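#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' The workhorse rank test behind every Increased/Unchanged designation.
#' Tie-free samples of moderate size use the exact U distribution;
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used. Complete ties (all values equal) return 1.
#'
#' @param x,y Numeric vectors, each length >= 1.
#' @return One-sided p-value in (0, 1].
#' @export
mann_whitney_one_sided <- function(x, y) {
  mwu_p(x, y, alternative = "greater")
}

#' Two-sided Mann-Whitney comparison of fold-change distributions
#'
#' Used for genome-wide fold-change comparisons between conditions;
#' symmetric in its arguments.
#'
#' @param fc_a,fc_b Numeric vectors, each length >= 1.
#' @return Two-sided p-value in (0, 1].
#' @export
compare_fc_distributions <- function(fc_a, fc_b) {
  mwu_p(fc_a, fc_b, alternative = "two.sided")
}

mwu_p <- function(x, y, alternative) {
  if (length(x) < 1 || length(y) < 1) stop("empty sample")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite value")
  if (all(c(x, y) == x[1])) return(1)  # degenerate: no rank information
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}
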