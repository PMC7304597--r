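# Per-cluster report bundles, run summaries, size distributions,
# unknown-gene accounting and cross-species GO set comparisons.

.calls_of <- function(x) {
  if (inherits(x, "FNTDCCallSet")) x$calls
  else if (inherits(x, "FNTDCCall")) list(x)
  else x
}

# Truncate (not round) to two decimals; per-cluster means are reported
# this way. Rounds at the 6th decimal first so that exact decimal
# quotients are not pushed below the truncation boundary by binary
# representation error.
.trunc2 <- function(x) trunc(round(x * 100, 6)) / 100

#' Per-cluster mean from a total and a call count
#'
#' `total / n_calls`, truncated to two decimals (17.567 -> 17.56).
#'
#' @param total Summed quantity over all calls.
#' @param n_calls Number of calls.
#' @return Numeric mean, truncated to two decimals.
#' @export
per_cluster_mean <- function(total, n_calls) .trunc2(total / n_calls)

#' Flat table of cluster calls
#'
#' @param calls An `FNTDCCallSet`, a single `FNTDCCall`, or a list of
#'   calls.
#' @return Data frame with one row per call: ordinal, name, chromosome,
#'   span, top GO term and P-value, and the call's size counters.
#' @export
calls_table <- function(calls) {
  calls <- .calls_of(calls)
  if (!length(calls))
    return(data.frame(ordinal = integer(), name = character(),
                      chromosome = character(), span_start = integer(),
                      span_end = integer(), top_go = character(),
                      top_p = double(), n_terms = integer(),
                      n_bp_genes = integer(), n_all_genes = integer(),
                      n_removed = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(calls, function(x) data.frame(
    ordinal = x$ordinal, name = x$name, chromosome = x$chromosome,
    span_start = x$span_bp[[1]], span_end = x$span_bp[[2]],
    top_go = x$top_go, top_p = x$top_p, n_terms = nrow(x$rows),
    n_bp_genes = length(x$member_bp_genes),
    n_all_genes = x$n_span_genes,
    n_removed = length(x$removed_tandem), stringsAsFactors = FALSE)))
}

#' Write the call table as TSV
#' @param calls Calls (see [calls_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_table <- function(calls, path) {
  utils::write.table(calls_table(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write call spans as a BED6 track
#'
#' Converts the 1-based inclusive spans to BED's 0-based half-open
#' convention. The score column is `-10 log10(P)` capped at 1000.
#'
#' @inheritParams write_calls_table
#' @return `path`, invisibly.
#' @export
write_bed_track <- function(calls, path) {
  tab <- calls_table(calls)
  bed <- data.frame(tab$chromosome, tab$span_start - 1L, tab$span_end,
                    tab$name, pmin(1000L, round(-10 * log10(tab$top_p))),
                    ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.gene_table_columns <- c(
  "Gene.stable.ID", "Sequence_desc.", "TERMS", "Chromosome.scaffold.name",
  "Gene.start..bp.", "Gene.end..bp.", "Strand", "Sequence_length")

.gene_table <- function(genes, domains = c("go_bp", "go_mf", "go_cc")) {
  terms <- vapply(seq_len(nrow(genes)), function(i)
    paste(unlist(genes[i, domains], use.names = FALSE), collapse = "; "),
    "")
  out <- data.frame(genes$gene_id,
                    ifelse(is.na(genes$description), "", genes$description),
                    terms, genes$chromosome, genes$start, genes$end,
                    genes$strand, genes$protein_length,
                    stringsAsFactors = FALSE)
  names(out) <- .gene_table_columns
  out
}

#' Write a per-cluster report bundle
#'
#' Emits the six per-cluster files: `SUMMARY_OVER` (enrichment rows),
#' `DATA_GENES_WITH_BP` (member genes carrying GO-BP),
#' `DATA_ALLGENES` (every gene whose span intersects the call span),
#' `REMOVED_BLAST` (collapsed tandem gene ids, or `NONE`),
#' `BLAST____FILTR_` (hits passing the stringency setting) and
#' `BLAST____EVERYTHING` (all hits at E <= 10 among the member proteins,
#' aligned exhaustively). A pairwise percent-identity matrix of the member
#' proteins is written alongside in place of a multiple-alignment figure.
#'
#' @param call An `FNTDCCall`.
#' @param catalog The `GeneCatalog` the call was made on.
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to `FNTDC<ordinal>`.
#' @return Named character vector of file paths (class
#'   `ClusterFileBundle`), invisibly.
#' @export
write_bundle <- function(call, catalog, out_dir,
                         prefix = sprintf("FNTDC%03d", call$ordinal)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(suffix) file.path(out_dir, paste0(prefix, "_", suffix))
  paths <- c(summary_over = path("SUMMARY_OVER.tsv"),
             data_genes_with_bp = path("DATA_GENES_WITH_BP.tsv"),
             data_allgenes = path("DATA_ALLGENES.tsv"),
             removed_blast = path("REMOVED_BLAST.tsv"),
             blast_filtr = path("BLAST____FILTR_.tsv"),
             blast_everything = path("BLAST____EVERYTHING.tsv"),
             identity_matrix = path("IDENTITY_MATRIX.tsv"))

  so <- data.frame(call$rows$go_id, call$rows$p_value,
                   call$rows$odds_ratio, call$rows$exp_count,
                   call$rows$count, call$rows$size,
                   ifelse(is.na(call$rows$term), "", call$rows$term),
                   stringsAsFactors = FALSE)
  names(so) <- c("GOBPID", "P-value", "OddsRatio", "ExpCount", "Count",
                 "Size", "Term")
  utils::write.table(so, paths[["summary_over"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  members <- catalog$genes[match(call$member_bp_genes,
                                 catalog$genes$gene_id), , drop = FALSE]
  span_g <- .span_genes(catalog, call$chromosome, call$span_bp[[1]],
                        call$span_bp[[2]])
  utils::write.table(.gene_table(members, domains = "go_bp"),
                     paths[["data_genes_with_bp"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(.gene_table(span_g), paths[["data_allgenes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(if (length(call$removed_tandem)) call$removed_tandem
             else "NONE", paths[["removed_blast"]])

  hits <- align_window(members, setting = NULL)  # exhaustive, for the dump
  write_blast_tsv(hits[passes_setting(hits, call$setting), , drop = FALSE],
                  paths[["blast_filtr"]])
  write_blast_tsv(hits, paths[["blast_everything"]])

  ids <- members$gene_id[!is.na(members$protein)]
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(hits))) {
    m[hits$query_id[[i]], hits$subject_id[[i]]] <-
      m[hits$subject_id[[i]], hits$query_id[[i]]] <-
      round(hits$identity_pct[[i]], 2)
  }
  utils::write.table(cbind(gene_id = rownames(m), as.data.frame(m)),
                     paths[["identity_matrix"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(structure(paths, class = "ClusterFileBundle"))
}

#' Read back a cluster bundle's enrichment rows and gene lists
#'
#' @param out_dir Directory holding the bundle.
#' @param prefix The bundle's file-name prefix.
#' @return List with `rows` (enrichment data frame in [enrich_window()]
#'   layout), `member_bp_genes`, `all_genes`, `removed`.
#' @export
read_bundle <- function(out_dir, prefix) {
  path <- function(suffix) file.path(out_dir, paste0(prefix, "_", suffix))
  so <- utils::read.delim(path("SUMMARY_OVER.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  rows <- data.frame(go_id = so$GOBPID, p_value = so$`P-value`,
                     odds_ratio = so$OddsRatio, exp_count = so$ExpCount,
                     count = so$Count, size = so$Size,
                     term = ifelse(nzchar(so$Term), so$Term, NA),
                     stringsAsFactors = FALSE)
  with_bp <- utils::read.delim(path("DATA_GENES_WITH_BP.tsv"),
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  allg <- utils::read.delim(path("DATA_ALLGENES.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  removed <- readLines(path("REMOVED_BLAST.tsv"))
  list(rows = rows, member_bp_genes = with_bp$Gene.stable.ID,
       all_genes = allg$Gene.stable.ID,
       removed = if (identical(removed, "NONE")) character() else removed)
}

#' Cluster size distributions
#'
#' Per call: span in kb (`(end - start + 1) / 1000`), the number of genes
#' whose span intersects the call span (tandem duplicates are not
#' excluded), and the subset of those carrying GO-BP.
#'
#' @param calls Calls (see [calls_table()]).
#' @param catalog The `GeneCatalog`.
#' @return List with `per_call` (data frame: `ordinal`, `span_kb`,
#'   `n_genes`, `n_bp_genes`) and `histograms` (list of three
#'   [graphics::hist()]-style count tables).
#' @export
size_distributions <- function(calls, catalog) {
  calls <- .calls_of(calls)
  if (!length(calls)) stop("no calls")
  per_call <- do.call(rbind, lapply(calls, function(x) {
    span_g <- .span_genes(catalog, x$chromosome, x$span_bp[[1]],
                          x$span_bp[[2]])
    data.frame(ordinal = x$ordinal,
               span_kb = (x$span_bp[[2]] - x$span_bp[[1]] + 1) / 1000,
               n_genes = nrow(span_g),
               n_bp_genes = sum(lengths(span_g$go_bp) > 0))
  }))
  histograms <- lapply(per_call[c("span_kb", "n_genes", "n_bp_genes")],
                       function(v) table(cut(v, breaks = pretty(v, 10))))
  list(per_call = per_call, histograms = histograms)
}

#' Unknown-gene accounting over call spans
#'
#' Totals and per-cluster means (truncated to two decimals) of all genes,
#' genes lacking GO-BP, and genes lacking any GO tag, over the spans of
#' the calls. Interspersed unannotated genes are candidate cluster members
#' by co-localization; this summary quantifies them.
#'
#' @param calls Calls (see [calls_table()]).
#' @param catalog The `GeneCatalog`.
#' @return List with `n_calls`, `total_genes`, `total_no_bp`,
#'   `total_no_go`, `mean_genes`, `mean_no_bp`, `mean_no_go`.
#' @export
unknown_gene_stats <- function(calls, catalog) {
  calls <- .calls_of(calls)
  if (!length(calls)) stop("no calls")
  tot <- c(genes = 0L, no_bp = 0L, no_go = 0L)
  for (x in calls) {
    span_g <- .span_genes(catalog, x$chromosome, x$span_bp[[1]],
                          x$span_bp[[2]])
    no_bp <- lengths(span_g$go_bp) == 0
    no_go <- no_bp & lengths(span_g$go_mf) == 0 &
      lengths(span_g$go_cc) == 0
    tot <- tot + c(nrow(span_g), sum(no_bp), sum(no_go))
  }
  n <- length(calls)
  list(n_calls = n, total_genes = unname(tot[["genes"]]),
       total_no_bp = unname(tot[["no_bp"]]),
       total_no_go = unname(tot[["no_go"]]),
       mean_genes = per_cluster_mean(tot[["genes"]], n),
       mean_no_bp = per_cluster_mean(tot[["no_bp"]], n),
       mean_no_go = per_cluster_mean(tot[["no_go"]], n))
}

#' Venn region counts for per-genome GO term sets
#'
#' For 2-4 genomes, counts every Venn region (2^g - 1 regions). Region
#' counts sum to the size of the union of all input sets.
#'
#' @param go_sets Named list (2-4 elements) of character vectors of GO
#'   ids, e.g. the GO tags associated with each genome's calls.
#' @return List with `regions` (data frame: `region` as genome names
#'   joined by `&`, `count`), `set_sizes` (per-genome set sizes) and
#'   `membership` (data frame: one row per term in the union, one logical
#'   column per genome).
#' @export
go_set_comparison <- function(go_sets) {
  if (length(go_sets) < 2 || length(go_sets) > 4)
    stop("go_set_comparison expects 2 to 4 genomes")
  if (is.null(names(go_sets)) || any(!nzchar(names(go_sets))))
    stop("go_sets must be named")
  go_sets <- lapply(go_sets, unique)
  universe <- sort(unique(unlist(go_sets, use.names = FALSE)))
  member <- vapply(go_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(go_sets)))
  key <- apply(member, 1, function(r)
    paste(names(go_sets)[r], collapse = "&"))
  g <- length(go_sets)
  all_regions <- unlist(lapply(seq_len(g), function(k)
    utils::combn(names(go_sets), k, paste, collapse = "&",
                 simplify = FALSE)))
  counts <- table(factor(key, levels = all_regions))
  regions <- data.frame(region = all_regions,
                        count = as.integer(counts[all_regions]),
                        stringsAsFactors = FALSE)
  list(regions = regions,
       set_sizes = vapply(go_sets, length, 0L),
       membership = data.frame(go_id = universe, member,
                               stringsAsFactors = FALSE,
                               row.names = NULL))
}

#' Write a single-worksheet run summary
#'
#' One TSV per run condition: the call table joined with per-call size and
#' unknown-gene counters, plus a BED track of call spans.
#'
#' @param calls An `FNTDCCallSet`.
#' @param catalog The `GeneCatalog`.
#' @param dir Output directory.
#' @param name Base file name (default from setting and threshold).
#' @return Named character vector of written paths, invisibly.
#' @export
write_run_summary <- function(calls, catalog, dir, name = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- calls$config
  if (is.null(name))
    name <- sprintf("summary_%s_P%g", cfg$setting$name, cfg$p_threshold)
  tab <- calls_table(calls)
  if (nrow(tab) > 0) {
    sizes <- size_distributions(calls, catalog)$per_call
    tab$span_kb <- sizes$span_kb
    no_bp <- integer(nrow(tab)); no_go <- integer(nrow(tab))
    for (i in seq_along(calls$calls)) {
      x <- calls$calls[[i]]
      span_g <- .span_genes(catalog, x$chromosome, x$span_bp[[1]],
                            x$span_bp[[2]])
      nb <- lengths(span_g$go_bp) == 0
      no_bp[[i]] <- sum(nb)
      no_go[[i]] <- sum(nb & lengths(span_g$go_mf) == 0 &
                          lengths(span_g$go_cc) == 0)
    }
    tab$n_no_bp <- no_bp
    tab$n_no_go <- no_go
  }
  paths <- c(summary = file.path(dir, paste0(name, ".tsv")),
             bed = file.path(dir, paste0(name, ".bed")))
  utils::write.table(tab, paths[["summary"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed_track(calls, paths[["bed"]])
  invisible(paths)
}
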