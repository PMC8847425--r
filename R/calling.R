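DYNAMIC_CODES <- c("IUI", "IUU", "UII", "UIU")
PATTERN_CLASSES <- c("GP1", "GP2", "GP3", "GP4", "static")

#' Thresholds for Increased/Unchanged calling
#'
#' A unit is designated Increased (I) in a condition when the one-sided
#' Mann-Whitney p-value of ChIP vs Input bins is below `alpha` AND the
#' region fold-change exceeds `fc_min`; otherwise Unchanged (U). The
#' conjunction is strict: a strong p-value cannot rescue a fold-change at
#' or below `fc_min`. Units with fewer than `min_bins` bins carry no
#' usable rank information and are called U with a low-coverage flag.
#'
#' @param alpha Significance threshold on the raw one-sided p (default 0.05).
#' @param fc_min Fold-change that must be exceeded (default 1.5).
#' @param consistency_alpha Threshold for the peak-level fold-change
#'   consistency filter (default 0.05).
#' @param pseudocount CPM pseudocount for fold-changes (default 0.25).
#' @param min_bins Minimum bins for an informative call (default 4).
#' @return A `call_parameters` list.
#' @export
call_parameters <- function(alpha = 0.05, fc_min = 1.5,
                            consistency_alpha = 0.05, pseudocount = 0.25,
                            min_bins = 4) {
  stopifnot(alpha > 0, alpha < 1, fc_min > 0, consistency_alpha > 0,
            consistency_alpha < 1, pseudocount > 0, min_bins >= 1)
  structure(list(alpha = alpha, fc_min = fc_min,
                 consistency_alpha = consistency_alpha,
                 pseudocount = pseudocount, min_bins = min_bins),
            class = "call_parameters")
}

#' Increased/Unchanged designation for one region in one condition
#'
#' @param chip_bins,input_bins Equal-length CPM bin vectors over the same
#'   region and bin grid.
#' @param params A [call_parameters()].
#' @return List with `designation` (`"I"` or `"U"`), `p_value`,
#'   `fold_change`, and `low_coverage`.
#' @export
iu_call <- function(chip_bins, input_bins, params = call_parameters()) {
  rfc <- region_fold_change(chip_bins, input_bins, params$pseudocount)
  if (length(chip_bins) < params$min_bins) {
    return(list(designation = "U", p_value = NA_real_,
                fold_change = rfc$fc, low_coverage = TRUE))
  }
  p <- mann_whitney_one_sided(chip_bins, input_bins)
  list(designation = if (p < params$alpha && rfc$fc > params$fc_min) "I" else "U",
       p_value = p, fold_change = rfc$fc, low_coverage = FALSE)
}

#' Classify a three-condition I/U code
#'
#' Condition order is (reference, disease, rescue). The four dynamic
#' codes are IUI, IUU, UII, UIU -> classes 1-4 (prefix GP for genes, PP
#' for peaks); the remaining four codes are `static`.
#'
#' @param code String over {I, U}, one letter per condition, length 3.
#' @param unit_kind `"gene"` or `"peak"`.
#' @return Class label, e.g. `"GP1"` or `"static"`.
#' @export
classify_code <- function(code, unit_kind = c("gene", "peak")) {
  unit_kind <- match.arg(unit_kind)
  if (!is.character(code) || length(code) != 1 || nchar(code) != 3 ||
      grepl("[^IU]", code)) {
    stop("code must be a length-3 string over {I, U}: ", deparse(code))
  }
  i <- match(code, DYNAMIC_CODES)
  if (is.na(i)) return("static")
  paste0(if (unit_kind == "gene") "GP" else "PP", i)
}

#' Peak-level fold-change consistency filter
#'
#' For a dynamic code, requires the per-bin log2 fold-change of EVERY
#' Increased condition to be stochastically greater than that of EVERY
#' Unchanged condition (one-sided Mann-Whitney p < `consistency_alpha`
#' for each (I, U) pair). All-I or all-U codes pass vacuously.
#'
#' @param log2fc_by_condition Named list of equal-length per-bin log2
#'   fold-change vectors, names = conditions in code order.
#' @param code The unit's I/U code (one letter per list element).
#' @param consistency_alpha Pairwise significance threshold.
#' @return `TRUE` if every (I, U) pair passes.
#' @export
consistency_filter <- function(log2fc_by_condition, code,
                               consistency_alpha = 0.05) {
  letters_ <- strsplit(code, "")[[1]]
  if (length(letters_) != length(log2fc_by_condition)) {
    stop("code length does not match number of conditions")
  }
  lens <- lengths(log2fc_by_condition)
  if (length(unique(lens)) != 1) stop("fold-change vectors differ in length")
  i_idx <- which(letters_ == "I")
  u_idx <- which(letters_ == "U")
  for (i in i_idx) {
    for (u in u_idx) {
      p <- mann_whitney_one_sided(log2fc_by_condition[[i]],
                                  log2fc_by_condition[[u]])
      if (p >= consistency_alpha) return(FALSE)
    }
  }
  TRUE
}

check_tracks <- function(tracks) {
  if (length(tracks) != 3) stop("exactly 3 conditions are required")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("tracks must be named by condition")
  }
  for (cond in names(tracks)) {
    pair <- tracks[[cond]]
    if (!all(c("chip", "input") %in% names(pair))) {
      stop("condition '", cond, "' needs both a chip and an input track")
    }
    for (ch in c("chip", "input")) {
      if (!inherits(pair[[ch]], "binned_track")) {
        stop("condition '", cond, "' ", ch, " is not a binned_track")
      }
    }
  }
  bs <- unique(unlist(lapply(tracks, function(p)
    c(p$chip$bin_size, p$input$bin_size))))
  if (length(bs) != 1) stop("all tracks must share one bin_size")
  lapply(tracks, function(p) lapply(p, normalize_cpm))
}

call_units <- function(tracks, units, params, unit_kind,
                       consistency = (unit_kind == "peak"),
                       windower = NULL) {
  tracks <- check_tracks(tracks)
  conds <- names(tracks)
  chrom_sizes <- tracks[[1]]$chip$chrom_sizes
  rows <- vector("list", nrow(units))
  skipped <- character(0)
  for (i in seq_len(nrow(units))) {
    unit <- units[i, ]
    region <- if (is.null(windower)) unit else {
      r <- tryCatch(windower(unit), error = function(e) conditionMessage(e))
      if (is.character(r)) { skipped <- c(skipped, unit$name); next }
      r
    }
    calls <- lapply(conds, function(cond) {
      chip <- extract_bins(tracks[[cond]]$chip, region)
      input <- extract_bins(tracks[[cond]]$input, region)
      c(iu_call(chip, input, params),
        list(log2fc = region_fold_change(chip, input,
                                         params$pseudocount)$log2fc))
    })
    names(calls) <- conds
    code <- paste(vapply(calls, `[[`, "", "designation"), collapse = "")
    label <- classify_code(code, unit_kind)
    cpass <- NA
    if (consistency && code %in% DYNAMIC_CODES) {
      cpass <- consistency_filter(lapply(calls, `[[`, "log2fc"), code,
                                  params$consistency_alpha)
      if (!cpass) label <- "static"
    }
    row <- data.frame(unit_id = unit$name, code = code, class = label,
                      consistency_pass = cpass,
                      low_coverage = any(vapply(calls, `[[`, TRUE,
                                                "low_coverage")),
                      stringsAsFactors = FALSE)
    for (cond in conds) {
      row[[paste0("p_", cond)]] <- calls[[cond]]$p_value
      row[[paste0("fc_", cond)]] <- calls[[cond]]$fold_change
      row[[paste0("call_", cond)]] <- calls[[cond]]$designation
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no unit could be evaluated")
  # BH-adjusted q per condition: reported for transparency, never used
  # for the I/U designation itself
  for (cond in conds) {
    out[[paste0("q_", cond)]] <- stats::p.adjust(out[[paste0("p_", cond)]],
                                                 method = "BH")
  }
  rownames(out) <- NULL
  structure(out, class = c("pattern_calls", "data.frame"),
            unit_kind = unit_kind, conditions = conds, params = params,
            skipped = skipped)
}

#' Gene-based pattern (GP) calling across three conditions
#'
#' For each gene: build its quantification window, extract ChIP and Input
#' CPM bins per condition, designate I/U per condition, form the
#' three-letter code in condition order, and classify (GP1-GP4 or
#' static). Gene mode evaluates genes directly and does not apply the
#' peak consistency filter (set `consistency = TRUE` to override).
#' Genes whose window is invalid are skipped and listed in the
#' `skipped` attribute. Raw tracks are CPM-normalized on the fly.
#'
#' @param tracks Named list of 3 conditions, in (reference, disease,
#'   rescue) order; each element a list with `chip` and `input`
#'   [binned_track()]s.
#' @param genes Gene data.frame from [read_gene_annotation()].
#' @param spec A [window_spec()].
#' @param params A [call_parameters()].
#' @param consistency Apply the peak-level consistency filter (default
#'   `FALSE` in gene mode).
#' @return A `pattern_calls` data.frame: `unit_id`, `code`, `class`, and
#'   per-condition `p_`, `fc_`, `call_`, `q_` columns.
#' @export
call_gene_patterns <- function(tracks, genes, spec = window_spec(),
                               params = call_parameters(),
                               consistency = FALSE) {
  chrom_sizes <- tracks[[1]]$chip$chrom_sizes
  call_units(tracks, genes, params, "gene", consistency = consistency,
             windower = function(g) gene_window(g, spec, chrom_sizes))
}

#' Peak-based pattern (PP) calling across three conditions
#'
#' As [call_gene_patterns()] but over peak intervals directly, and with
#' the fold-change consistency filter applied: a peak whose dynamic code
#' fails the filter is demoted to `static` with
#' `consistency_pass = FALSE`.
#'
#' @param tracks Named condition list as in [call_gene_patterns()].
#' @param peaks Peak data.frame from [read_bed()].
#' @param params A [call_parameters()].
#' @param consistency Apply the filter (default `TRUE`).
#' @return A `pattern_calls` data.frame.
#' @export
call_peak_patterns <- function(tracks, peaks, params = call_parameters(),
                               consistency = TRUE) {
  call_units(tracks, peaks, params, "peak", consistency = consistency)
}

#' @export
print.pattern_calls <- function(x, ...) {
  kind <- attr(x, "unit_kind")
  dyn <- sum(x$class != "static")
  cat(sprintf("pattern_calls: %d %ss over conditions (%s); %d dynamic, %d static\n",
              nrow(x), kind, paste(attr(x, "conditions"), collapse = ", "),
              dyn, nrow(x) - dyn))
  if (length(attr(x, "skipped"))) {
    cat("skipped (invalid window):", length(attr(x, "skipped")), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
summary.pattern_calls <- function(object, ...) {
  summarize_patterns(object)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize dynamic pattern classes
#'
#' Counts and integer percentages per dynamic class, percentages taken
#' over all dynamic units and rounded half away from zero, with a total
#' row. Accepts either a `pattern_calls` table or a named count vector.
#'
#' @param assignments A `pattern_calls` data.frame, or a named numeric
#'   vector of per-class counts (e.g. `c(GP1 = 2293, GP2 = 786, ...)`).
#' @return data.frame with columns `class`, `count`, `percent`.
#' @export
summarize_patterns <- function(assignments) {
  if (inherits(assignments, "pattern_calls") || is.data.frame(assignments)) {
    cls <- assignments$class[assignments$class != "static"]
    counts <- table(cls)
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    counts <- assignments[names(assignments) != "static"]
  }
  if (length(counts) == 0 || sum(counts) == 0) {
    warning("no dynamic units to summarize")
    return(data.frame(class = character(0), count = numeric(0),
                      percent = numeric(0)))
  }
  counts <- counts[order(names(counts))]
  total <- sum(counts)
  out <- data.frame(class = c(names(counts), "total"),
                    count = c(as.numeric(counts), total),
                    percent = c(round_half_away(100 * counts / total), 100),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genome-wide per-gene fold-change table
#'
#' One row per gene, one ChIP-vs-Input fold-change column per condition,
#' computed over the gene's quantification window. This is the input to
#' cross-condition fold-change distribution comparisons.
#'
#' @inheritParams call_gene_patterns
#' @return data.frame with `gene_id` and one `fc_<condition>` column per
#'   condition; skipped genes recorded in the `skipped` attribute.
#' @export
genomewide_fc_table <- function(tracks, genes, spec = window_spec(),
                                params = call_parameters()) {
  tracks <- check_tracks(tracks)
  conds <- names(tracks)
  chrom_sizes <- tracks[[1]]$chip$chrom_sizes
  gw <- gene_windows(genes, spec, chrom_sizes)
  windows <- gw$windows
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    region <- windows[i, ]
    fcs <- vapply(conds, function(cond) {
      region_fold_change(extract_bins(tracks[[cond]]$chip, region),
                         extract_bins(tracks[[cond]]$input, region),
                         params$pseudocount)$fc
    }, 0)
    as.data.frame(c(list(gene_id = region$name), as.list(setNames(
      fcs, paste0("fc_", conds)))), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- gw$skipped
  out
}
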