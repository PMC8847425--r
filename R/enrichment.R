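#' Genome-wide background probability of a pattern
#'
#' The background probability of a pattern class is the fraction of all
#' assessed genes that carry it — learned from the genome-wide pattern
#' table, not from any annotation universe.
#'
#' @param assignments A `pattern_calls` table (or any data.frame with
#'   `gene_id`/`unit_id` and `class` columns).
#' @param pattern Class label, e.g. `"GP1"`.
#' @return Background probability in \[0, 1\].
#' @export
background_probability <- function(assignments, pattern) {
  if (nrow(assignments) == 0) stop("no genome-wide assignments")
  mean(assignments$class == pattern)
}

#' Binomial enrichment p-value
#'
#' Probability, under the null that each of the `n` list members follows
#' the pattern independently with the genome-wide background probability
#' `p_b`, of seeing MORE than `k` members with the pattern:
#' `P(X > k), X ~ Binomial(n, p_b)` — the survival form of
#' `1 - sum_{i=0..k} C(n,i) p_b^i (1-p_b)^(n-i)`. Strictly greater than
#' `k`: a list can never be enriched for a pattern it does not exceed.
#'
#' @param n Size of the gene list of interest (after intersection with
#'   the assessed universe).
#' @param k Members of the list carrying the pattern.
#' @param p_b Background probability of the pattern.
#' @return p-value in \[0, 1\]; vectorized over `n`, `k`, `p_b`.
#' @export
binomial_enrichment_p <- function(n, k, p_b) {
  if (any(k > n)) stop("k > n")
  if (any(k < 0) || any(n < 0)) stop("negative count")
  if (any(p_b < 0) || any(p_b > 1)) stop("p_b outside [0, 1]")
  p <- stats::pbinom(k, size = n, prob = p_b, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Pattern enrichment of gene sets
#'
#' For each (pattern, gene set) pair: intersect the set with the universe
#' of genes that received a pattern assessment, count members following
#' the pattern, and compute the binomial enrichment p-value against the
#' genome-wide background. Sets disjoint from the universe are skipped
#' with a warning. Results are sorted by ascending p; a
#' Benjamini-Hochberg q is added within each pattern.
#'
#' @param assignments Genome-wide `pattern_calls` table.
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param patterns Pattern classes to test (default the four dynamic
#'   gene classes).
#' @return data.frame: `set`, `pattern`, `n`, `k`, `p_b`, `p_value`, `q`.
#' @export
enrich_gene_sets <- function(assignments, gene_sets,
                             patterns = c("GP1", "GP2", "GP3", "GP4")) {
  stopifnot(length(gene_sets) > 0)
  universe <- assignments$unit_id
  if (is.null(universe)) universe <- assignments$gene_id
  if (length(universe) == 0) stop("empty assessment universe")
  cls <- setNames(assignments$class, universe)
  rows <- list()
  for (set_name in names(gene_sets)) {
    members <- intersect(gene_sets[[set_name]], universe)
    if (length(members) == 0) {
      warning("gene set '", set_name, "' is disjoint from the universe; skipped")
      next
    }
    for (pt in patterns) {
      p_b <- background_probability(assignments, pt)
      k <- sum(cls[members] == pt)
      rows[[length(rows) + 1]] <- data.frame(
        set = set_name, pattern = pt, n = length(members), k = k,
        p_b = p_b, p_value = binomial_enrichment_p(length(members), k, p_b),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no testable gene set")
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (pt in unique(out$pattern)) {
    sel <- out$pattern == pt
    out$q[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out <- out[order(out$p_value, out$set, out$pattern), ]
  rownames(out) <- NULL
  out
}
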