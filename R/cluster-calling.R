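# Orchestrates the scan: per master window, collapse tandem duplicates and
# run GO-BP enrichment in every sub-window, keep the sub-window with the
# lowest P-value, and emit at most one cluster call per master window.

#' Scan configuration
#'
#' Defaults follow the intermediate reference condition: master window of
#' 24 GO-BP genes, the 13-sub-window default scheme, tandem stringency
#' setting_2 (70% identity, ratio 0.7) and a raw hypergeometric P-value
#' threshold of 1e-6 (no multiple-testing correction; the method filters on
#' raw P). The threshold is applied after best-sub-window selection.
#'
#' @param master_size Genes per master window.
#' @param scheme A [subwindow_scheme()].
#' @param setting A [tandem_setting()].
#' @param p_threshold Maximum enrichment P-value for a call.
#' @param min_count Minimum genes sharing a GO-BP term (after collapse)
#'   for the term to support a call.
#' @param propagate_go Propagate GO-BP terms to ancestors when building
#'   catalogs (recorded for the manifest; [read_genome()] does the work).
#' @param seed Seed recorded in run manifests. The scan itself is
#'   deterministic.
#' @return An object of class `ScanConfig`.
#' @export
scan_config <- function(master_size = 24L, scheme = subwindow_scheme(),
                        setting = tandem_setting(2L), p_threshold = 1e-6,
                        min_count = 3L, propagate_go = FALSE, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold <= 1, min_count >= 1)
  structure(list(master_size = as.integer(master_size), scheme = scheme,
                 setting = setting, p_threshold = p_threshold,
                 min_count = as.integer(min_count),
                 propagate_go = propagate_go, seed = as.integer(seed)),
            class = "ScanConfig")
}

.window_gene_rows <- function(catalog, master) {
  idx <- catalog$bp_order[[master$chromosome]]
  idx <- idx[(master$bp_start_rank + 1L):master$bp_end_rank]
  catalog$genes[idx, , drop = FALSE]
}

.span_genes <- function(catalog, chromosome, span_start, span_end) {
  g <- catalog$genes
  sel <- g$chromosome == chromosome & g$start <= span_end &
    g$end >= span_start
  g[sel, , drop = FALSE]
}

#' Evaluate one master window and call a cluster if enriched
#'
#' Pairwise protein hits are computed once for the master window and
#' reused by every sub-window. In each sub-window, tandem groups are
#' formed from the hits restricted to the sub-window's genes, collapsed to
#' their first-by-coordinate representatives, and the retained genes are
#' tested for GO-BP enrichment. The sub-window whose best term attains the
#' lowest P-value wins (ties: fewer genes, then smaller offset); a call is
#' returned only when that minimum P is at or below the configured
#' threshold (or unconditionally when `keep_candidate` is set, with the
#' pass/fail decision left to the caller).
#'
#' @param master A master window from [enumerate_master_windows()].
#' @param catalog The `GeneCatalog`.
#' @param config A [scan_config()].
#' @param hits Optional precomputed hit table for the master window's
#'   genes (external-aligner mode); computed internally when `NULL`.
#' @param keep_candidate Return the best candidate even when its P-value
#'   misses the threshold.
#' @return An `FNTDCCall` object, or `NULL` when no sub-window has a term
#'   shared by `min_count` genes (or, unless `keep_candidate`, when the
#'   best P misses the threshold).
#' @export
call_master_window <- function(master, catalog, config = scan_config(),
                               hits = NULL, keep_candidate = FALSE) {
  window_genes <- .window_gene_rows(catalog, master)
  if (is.null(hits))
    hits <- align_window(window_genes, setting = config$setting)
  subs <- enumerate_sub_windows(master, config$scheme)
  best <- NULL
  for (i in seq_len(nrow(subs))) {
    off <- subs$offset[[i]]; len <- subs$length[[i]]
    sub_genes <- window_genes[(off + 1L):(off + len), , drop = FALSE]
    groups <- tandem_groups(sub_genes, hits, config$setting)
    coll <- collapse_tandems(sub_genes, groups)
    rows <- enrich_window(coll$retained, catalog,
                          min_count = config$min_count, p_threshold = 1)
    if (nrow(rows) == 0) next
    p <- rows$p_value[[1]]
    if (is.null(best) || p < best$p ||
        (p == best$p && (len < best$len ||
                         (len == best$len && off < best$off)))) {
      best <- list(p = p, off = off, len = len, rows = rows,
                   removed = coll$removed, sub_genes = sub_genes)
    }
  }
  if (is.null(best)) return(NULL)
  if (!keep_candidate && best$p > config$p_threshold) return(NULL)
  members <- best$sub_genes
  span <- c(min(members$start), max(members$end))
  span_g <- .span_genes(catalog, master$chromosome, span[[1]], span[[2]])
  inter <- span_g[lengths(span_g$go_bp) == 0, , drop = FALSE]
  by_coord <- order(members$start, members$end, members$gene_id)
  first <- members$gene_id[by_coord[[1]]]
  last <- members$gene_id[by_coord[[length(by_coord)]]]
  structure(list(
    ordinal = NA_integer_,
    name = paste0(first, "_TO_", last),
    chromosome = master$chromosome,
    span_bp = span,
    sub_window = list(offset = best$off, length = best$len),
    master = master,
    member_bp_genes = members$gene_id,
    interspersed_genes = inter$gene_id,
    removed_tandem = best$removed,
    rows = best$rows,
    top_go = best$rows$go_id[[1]],
    top_p = best$p,
    n_span_genes = nrow(span_g),
    setting = config$setting,
    p_threshold = config$p_threshold
  ), class = "FNTDCCall")
}

#' Scan a genome for functional non-tandem-duplicated clusters
#'
#' Runs [call_master_window()] over every master window of every
#' chromosome, in chromosome then position order, and assigns ordinals to
#' the resulting calls. Deterministic: identical inputs and configuration
#' produce identical call sets.
#'
#' @param catalog A `GeneCatalog`.
#' @param config A [scan_config()].
#' @param keep_all Keep the best candidate of every master window
#'   regardless of the P threshold (callers can then re-filter with
#'   [filter_calls()], e.g. to compare thresholds without re-aligning).
#' @param verbose Log per-stage counts to stderr.
#' @return An object of class `FNTDCCallSet`.
#' @export
scan_genome <- function(catalog, config = scan_config(), keep_all = FALSE,
                        verbose = FALSE) {
  masters <- enumerate_master_windows(catalog, config$master_size)
  calls <- list()
  for (m in masters) {
    call <- call_master_window(m, catalog, config,
                               keep_candidate = keep_all)
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  if (verbose)
    message("scanned ", length(masters), " master windows; ",
            sum(vapply(calls, function(x)
              x$top_p <= config$p_threshold, NA)), " call(s) at P <= ",
            format(config$p_threshold))
  res <- structure(list(calls = calls, config = config,
                        n_master_windows = length(masters)),
                   class = "FNTDCCallSet")
  if (keep_all) res else filter_calls(res, config$p_threshold)
}

#' Re-filter a call set at a (possibly stricter) P-value threshold
#'
#' The enrichment threshold is applied after best-sub-window selection, so
#' call sets at nested thresholds share their winning sub-windows: the
#' calls at 1e-8 are a subset of the calls at 1e-6. This helper filters a
#' `keep_all` scan (or a previous call set) without re-scanning, filters
#' each call's enrichment rows to the threshold, and renumbers ordinals.
#'
#' @param callset An `FNTDCCallSet`.
#' @param p_threshold New threshold.
#' @return A new `FNTDCCallSet`.
#' @export
filter_calls <- function(callset, p_threshold) {
  keep <- Filter(function(x) x$top_p <= p_threshold, callset$calls)
  keep <- lapply(seq_along(keep), function(i) {
    x <- keep[[i]]
    x$ordinal <- i
    x$p_threshold <- p_threshold
    x$rows <- x$rows[x$rows$p_value <= p_threshold, , drop = FALSE]
    x
  })
  config <- callset$config
  config$p_threshold <- p_threshold
  structure(list(calls = keep, config = config,
                 n_master_windows = callset$n_master_windows),
            class = "FNTDCCallSet")
}

#' @export
print.FNTDCCall <- function(x, ...) {
  cat("FNTDC", if (!is.na(x$ordinal)) paste0("#", x$ordinal) else "",
      x$name, "\n")
  cat("  ", x$chromosome, ":", x$span_bp[[1]], "-", x$span_bp[[2]],
      " (", x$sub_window$length, " GO-BP genes, offset ",
      x$sub_window$offset, ")\n", sep = "")
  cat("  top GO:", x$top_go, " P =", format(x$top_p, digits = 4),
      "|", nrow(x$rows), "enriched term(s),",
      length(x$removed_tandem), "tandem gene(s) removed\n")
  invisible(x)
}

#' @export
print.FNTDCCallSet <- function(x, ...) {
  cat("FNTDCCallSet:", length(x$calls), "call(s) over",
      x$n_master_windows, "master window(s)\n")
  cat("  setting:", x$config$setting$name,
      "| P threshold:", format(x$config$p_threshold), "\n")
  invisible(x)
}
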