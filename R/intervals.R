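# Internal convention: all intervals are 0-based half-open [start, end),
# strand one of "+", "-", "*" (unstranded). Collections are plain
# data.frames with columns chrom, start, end, name, strand.

new_intervals <- function(chrom, start, end, name, strand = "*") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
}

validate_intervals <- function(df, require_strand = FALSE) {
  stopifnot(all(c("chrom", "start", "end", "name", "strand") %in% names(df)))
  if (any(!nzchar(df$chrom))) stop("interval with empty chromosome name")
  if (any(df$start < 0)) stop("interval with negative start")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("interval '%s': start (%d) >= end (%d)",
                 df$name[bad[1]], as.integer(df$start[bad[1]]),
                 as.integer(df$end[bad[1]])))
  }
  if (!all(df$strand %in% c("+", "-", "*"))) stop("invalid strand value")
  if (require_strand && any(df$strand == "*")) {
    stop("strand is required but missing for: ",
         paste(df$name[df$strand == "*"], collapse = ", "))
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate interval name: ", df$name[duplicated(df$name)][1])
  }
  rownames(df) <- NULL
  df
}

# 0-based half-open -> IRanges (1-based closed)
intervals_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}
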