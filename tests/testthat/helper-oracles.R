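# Independent oracles, deliberately brute-force: these never call the
# package code paths they are used to check.

# Mann-Whitney U with half-credit for ties
mwu_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact permutation p-value by enumeration of all C(n1+n2, n1) labelings
mwu_enum_p <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  comb <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(comb), n1)
  u_obs <- mwu_u_stat(x, y)
  us <- apply(idx, 2, function(ii) mwu_u_stat(comb[ii], comb[-ii]))
  if (alternative == "greater") {
    mean(us >= u_obs - 1e-9)
  } else {
    mu <- n1 * length(y) / 2
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  }
}

# Upper binomial tail by direct summation of pmf terms
binom_tail_oracle <- function(n, k, p) {
  if (k >= n) return(0)
  i <- (k + 1):n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Same tail via the literal one-minus-lower-sum form (cancellation-prone,
# only meaningful when the tail is not tiny)
binom_tail_complement_oracle <- function(n, k, p) {
  i <- 0:k
  1 - sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# All-pairs >=1 bp overlap sweep
brute_force_pairs <- function(peaks, windows) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] == windows$chrom[j] &&
          min(peaks$end[i], windows$end[j]) -
            max(peaks$start[i], windows$start[j]) >= 1) {
        rows[[length(rows) + 1]] <- data.frame(
          peak_id = peaks$name[i], gene_id = windows$name[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(0), gene_id = character(0)))
  }
  unique(do.call(rbind, rows))
}
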