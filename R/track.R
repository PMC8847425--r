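#' Construct a binned coverage track
#'
#' A `binned_track` holds per-chromosome fixed-width-bin intensity for one
#' sequencing library (one condition x channel). Values are raw read mass
#' until [normalize_cpm()] converts them to counts per million.
#'
#' @param bins Named list, one numeric vector per chromosome; vector `i`
#'   covers `[(i-1)*bin_size, i*bin_size)`.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths; every
#'   chromosome gets a (possibly all-zero) bin vector.
#' @param library_size Total read mass assigned to the library; defaults to
#'   the sum over all bins.
#' @param label Free-text label, conventionally `"<condition>.<channel>"`.
#' @param normalized Whether `bins` are already CPM.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(bins, bin_size, chrom_sizes, library_size = NULL,
                         label = "", normalized = FALSE) {
  stopifnot(is.list(bins), bin_size > 0, length(chrom_sizes) > 0)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be named")
  }
  full <- lapply(names(chrom_sizes), function(chr) {
    n <- ceiling(chrom_sizes[[chr]] / bin_size)
    v <- bins[[chr]]
    if (is.null(v)) v <- numeric(n)
    if (length(v) != n) stop("bin vector for ", chr, " has length ",
                             length(v), ", expected ", n)
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("non-finite or negative bin value on ", chr)
    }
    v
  })
  names(full) <- names(chrom_sizes)
  if (is.null(library_size)) library_size <- sum(vapply(full, sum, 0))
  if (!isTRUE(library_size > 0)) stop("library_size must be > 0")
  structure(list(bins = full, bin_size = bin_size,
                 chrom_sizes = chrom_sizes, library_size = library_size,
                 label = label, normalized = normalized),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track '%s': %d chromosome(s), bin %d bp, %s bins, library %.4g%s\n",
              x$label, length(x$bins), as.integer(x$bin_size),
              format(sum(lengths(x$bins)), big.mark = ","),
              x$library_size, if (x$normalized) " (CPM)" else " (raw)"))
  invisible(x)
}

#' Read a bedGraph file into a binned track
#'
#' bedGraph values are interpreted as per-bp depth, so a record contributes
#' `value * overlap_width` mass to each bin it touches (pro-rata by overlap
#' length). Total mass is conserved regardless of how records are
#' fragmented. The returned track is raw (un-normalized); `library_size`
#' is the total mass.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named numeric vector listing every chromosome the
#'   file may reference.
#' @param label Track label.
#' @return A raw [binned_track()].
#' @export
read_bedgraph_track <- function(path, bin_size, chrom_sizes, label = "") {
  cl <- content_lines(path)
  f <- split_fields(cl$lines)
  if (any(lengths(f) < 4)) {
    stop(sprintf("%s: line %d: bedGraph needs 4 columns",
                 path, cl$lineno[which(lengths(f) < 4)[1]]))
  }
  chrom <- vapply(f, `[`, "", 1L)
  start <- parse_int(vapply(f, `[`, "", 2L), "start", cl$lineno, path)
  end <- parse_int(vapply(f, `[`, "", 3L), "end", cl$lineno, path)
  value <- as.numeric(vapply(f, `[`, "", 4L))
  if (any(is.na(value))) stop(path, ": non-numeric value")
  if (any(value < 0)) {
    stop(sprintf("%s: line %d: negative value",
                 path, cl$lineno[which(value < 0)[1]]))
  }
  unknown <- !chrom %in% names(chrom_sizes)
  if (any(unknown)) {
    stop(sprintf("%s: line %d: unknown chromosome '%s'",
                 path, cl$lineno[which(unknown)[1]], chrom[which(unknown)[1]]))
  }
  beyond <- end > chrom_sizes[chrom]
  if (any(beyond)) {
    stop(sprintf("%s: line %d: interval extends beyond end of %s",
                 path, cl$lineno[which(beyond)[1]], chrom[which(beyond)[1]]))
  }
  if (any(start >= end)) {
    stop(sprintf("%s: line %d: start >= end",
                 path, cl$lineno[which(start >= end)[1]]))
  }
  bins <- lapply(names(chrom_sizes), function(chr)
    numeric(ceiling(chrom_sizes[[chr]] / bin_size)))
  names(bins) <- names(chrom_sizes)
  for (i in seq_along(chrom)) {
    b0 <- floor(start[i] / bin_size)
    b1 <- floor((end[i] - 1) / bin_size)
    idx <- b0:b1
    ov <- pmin((idx + 1) * bin_size, end[i]) - pmax(idx * bin_size, start[i])
    bins[[chrom[i]]][idx + 1] <- bins[[chrom[i]]][idx + 1] + value[i] * ov
  }
  binned_track(bins, bin_size, chrom_sizes, label = label)
}

#' Write a binned track as bedGraph
#'
#' Emits one record per non-zero bin with the value expressed as per-bp
#' depth (`mass / bin_width`), the inverse of [read_bedgraph_track()]'s
#' pro-rata convention. Output is deterministic.
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$bins)) {
    v <- track$bins[[chr]]
    nz <- which(v > 0)
    if (!length(nz)) next
    s <- (nz - 1) * track$bin_size
    e <- pmin(nz * track$bin_size, track$chrom_sizes[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, as.integer(s),
                       as.integer(e), v[nz] / (e - s)), con)
  }
  invisible(path)
}

#' Normalize a raw track to counts per million
#'
#' Each bin becomes `mass * 1e6 / library_size`. Already-normalized tracks
#' are returned unchanged.
#'
#' @param track A raw [binned_track()].
#' @return The CPM-scaled track.
#' @export
normalize_cpm <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  if (track$normalized) return(track)
  if (!isTRUE(track$library_size > 0)) stop("library_size must be > 0")
  track$bins <- lapply(track$bins, function(v) v * 1e6 / track$library_size)
  track$normalized <- TRUE
  track
}

#' Extract the bin vector overlapping an interval
#'
#' Returns, in genomic order, every bin fully or partially overlapping the
#' interval; boundary bins are included whole.
#'
#' @param track A [binned_track()].
#' @param interval One-row data.frame (or list) with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @return Numeric vector of bin values.
#' @export
extract_bins <- function(track, interval) {
  stopifnot(inherits(track, "binned_track"))
  chr <- as.character(interval$chrom[1])
  if (!chr %in% names(track$bins)) stop("unknown chromosome: ", chr)
  s <- interval$start[1]; e <- interval$end[1]
  if (s < 0 || e > track$chrom_sizes[[chr]] || s >= e) {
    stop("interval out of bounds on ", chr)
  }
  b0 <- floor(s / track$bin_size)
  b1 <- ceiling(e / track$bin_size) - 1
  track$bins[[chr]][(b0:b1) + 1]
}
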