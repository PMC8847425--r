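split_fields <- function(lines) strsplit(trimws(lines, "right"), "[ \t]+")

content_lines <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_int <- function(x, what, lineno, path) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(v != floor(v))) {
    bad <- lineno[which(is.na(v) | v != floor(v))[1]]
    stop(sprintf("%s: line %d: non-integer %s '%s'",
                 path, bad, what, x[which(is.na(v) | v != floor(v))[1]]))
  }
  v
}

#' Read a BED file of intervals
#'
#' Reads BED3 or better into a 0-based half-open interval table. Records
#' without a name column get synthesized names `peak_1`, `peak_2`, ... in
#' file order. Typical input is a broad-domain peak caller's island BED.
#'
#' @param path Path to a BED file (whitespace- or tab-separated, >= 3
#'   columns; `track`/`browser`/comment lines are ignored).
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (`"*"` when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cl <- content_lines(path)
  f <- split_fields(cl$lines)
  ncols <- lengths(f)
  if (length(f) == 0) stop(path, ": no records")
  if (any(ncols < 3)) {
    stop(sprintf("%s: line %d: fewer than 3 columns",
                 path, cl$lineno[which(ncols < 3)[1]]))
  }
  chrom <- vapply(f, `[`, "", 1L)
  start <- parse_int(vapply(f, `[`, "", 2L), "start", cl$lineno, path)
  end <- parse_int(vapply(f, `[`, "", 3L), "end", cl$lineno, path)
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("%s: line %d: start (%d) >= end (%d)",
                 path, cl$lineno[bad[1]], start[bad[1]], end[bad[1]]))
  }
  name <- ifelse(ncols >= 4, vapply(f, function(x) x[4], ""), NA_character_)
  miss <- is.na(name) | name == "."
  name[miss] <- paste0("peak_", which(miss))
  strand <- ifelse(ncols >= 6, vapply(f, function(x) x[6], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  validate_intervals(data.frame(
    chrom = chrom, start = start, end = end, name = name,
    strand = strand, stringsAsFactors = FALSE))
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()]: round-trips `chrom`, `start`, `end`, `name`,
#' `strand` exactly.
#'
#' @param intervals Interval data.frame (see [read_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- validate_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", df$chrom,
                   as.integer(df$start), as.integer(df$end), df$name,
                   ifelse(df$strand == "*", ".", df$strand))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations from BED6/BED12 or minimal GTF
#'
#' Every gene must carry a strand and a unique identifier. GTF coordinates
#' (1-based inclusive) are converted to the package's 0-based half-open
#' convention on read; only `gene` feature lines are used and the
#' `gene_id` attribute is the identifier.
#'
#' @param path Annotation file.
#' @param format `"bed"` or `"gtf"`. Default guesses from the extension.
#' @return A data.frame of stranded intervals with `gene_id` (== `name`).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  if (format == "bed") {
    cl <- content_lines(path)
    f <- split_fields(cl$lines)
    if (any(lengths(f) < 6)) {
      stop(sprintf("%s: line %d: gene BED needs >= 6 columns (strand required)",
                   path, cl$lineno[which(lengths(f) < 6)[1]]))
    }
    df <- data.frame(
      chrom = vapply(f, `[`, "", 1L),
      start = parse_int(vapply(f, `[`, "", 2L), "start", cl$lineno, path),
      end = parse_int(vapply(f, `[`, "", 3L), "end", cl$lineno, path),
      name = vapply(f, `[`, "", 4L),
      strand = vapply(f, `[`, "", 6L),
      stringsAsFactors = FALSE)
  } else {
    cl <- content_lines(path)
    f <- strsplit(cl$lines, "\t")
    f <- f[vapply(f, function(x) length(x) >= 8 && x[3] == "gene", TRUE)]
    if (length(f) == 0) stop(path, ": no 'gene' features found")
    attr9 <- vapply(f, function(x) if (length(x) >= 9) x[9] else "", "")
    m <- regmatches(attr9, regexpr('gene_id[ =]+"?[^";]+"?', attr9))
    if (length(m) != length(f) || any(!nzchar(m))) {
      stop(path, ": gene feature without gene_id attribute")
    }
    ids <- gsub('^gene_id[ =]+"?|"$', "", m)
    df <- data.frame(
      chrom = vapply(f, `[`, "", 1L),
      start = as.numeric(vapply(f, `[`, "", 4L)) - 1,  # 1-based -> 0-based
      end = as.numeric(vapply(f, `[`, "", 5L)),
      name = ids,
      strand = vapply(f, `[`, "", 7L),
      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop(path, ": duplicate gene_id: ", df$name[duplicated(df$name)][1])
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop(path, ": gene without strand: ",
         df$name[!df$strand %in% c("+", "-")][1])
  }
  df <- validate_intervals(df, require_strand = TRUE)
  df$gene_id <- df$name
  df
}

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV of chromosome name and length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  cl <- content_lines(path)
  f <- split_fields(cl$lines)
  if (any(lengths(f) < 2)) stop(path, ": chrom.sizes needs 2 columns")
  sizes <- as.numeric(vapply(f, `[`, "", 2L))
  if (any(is.na(sizes)) || any(sizes <= 0)) stop(path, ": invalid size")
  setNames(sizes, vapply(f, `[`, "", 1L))
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are dropped.
#'
#' @param path GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  cl <- content_lines(path)
  f <- strsplit(cl$lines, "\t")
  short <- which(lengths(f) < 3)
  if (length(short)) {
    stop(sprintf("%s: line %d: gene set with no members",
                 path, cl$lineno[short[1]]))
  }
  sets <- lapply(f, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(f, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop(path, ": duplicate set name")
  attr(sets, "description") <- setNames(vapply(f, `[`, "", 2L), names(sets))
  sets
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), header row, UTF-8, numeric
#' columns at 6 significant digits.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
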