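#' Read gene and transcript records from a GFF3 file
#'
#' Parses `gene` and `mRNA`/`transcript` features from a GFF3 file,
#' preserving 1-based inclusive coordinates and strand, and links each
#' transcript to its parent gene through the `Parent` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gff_records`: a list with elements
#'   `genes` (data frame: `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `description`) and `transcripts` (data frame:
#'   `isoform_id`, `gene_id`).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  for (i in which(body)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed GFF3 line ", i, ": expected >= 8 tab-separated fields")
    s <- suppressWarnings(as.integer(f[[4]])); e <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(s) || is.na(e))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
    if (e < s)
      stop("malformed GFF3 line ", i, ": end (", e, ") < start (", s, ")")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  if (!any(is_gene)) stop("no 'gene' features in ", path)
  desc <- if (!is.null(gr$description)) as.character(gr$description) else
    rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chromosome = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    description = desc[is_gene],
    stringsAsFactors = FALSE
  )
  if (anyNA(genes$gene_id)) stop("gene feature without ID attribute in ", path)
  parent <- vapply(gr$Parent[is_tx], function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, "")
  tx <- data.frame(
    isoform_id = as.character(gr$ID[is_tx]),
    gene_id = parent,
    stringsAsFactors = FALSE
  )
  if (anyNA(tx$gene_id) || !all(tx$gene_id %in% genes$gene_id))
    stop("mRNA/transcript feature with missing or unknown Parent gene in ", path)
  structure(list(genes = genes, transcripts = tx), class = "gff_records")
}

#' Read protein sequences from a FASTA file
#'
#' Sequence names are truncated at the first whitespace, so headers keyed by
#' isoform id with trailing free text are handled.
#'
#' @param path Path to a protein FASTA file.
#' @return A named [Biostrings::AAStringSet].
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  aa
}

#' Read a GO annotation table (TSV or GAF)
#'
#' Accepts either a tab-separated table with header columns
#' `id`, `go_id`, `go_domain` (values `BP`, `MF`, `CC`; `P`/`F`/`C` and the
#' long ontology names are normalised) and optional `term_name`, or a GAF
#' 2.x file (columns 2, 5 and 9 are used). Ids may be gene ids or isoform
#' ids; the mapping onto genes happens in [select_representative()].
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"`, `"tsv"`, `"gaf"`.
#' @return A data frame with columns `id`, `go_id`, `go_domain`, `term_name`.
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "!") ||
                  length(strsplit(first, "\t", fixed = TRUE)[[1]]) >= 15)
      "gaf" else "tsv"
  }
  if (format == "gaf") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 9)
    if (length(bad)) stop("GAF line with fewer than 9 columns: line ", bad[[1]])
    ann <- data.frame(
      id = vapply(f, `[[`, "", 2L),
      go_id = vapply(f, `[[`, "", 5L),
      go_domain = vapply(f, `[[`, "", 9L),
      term_name = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("id", "go_id", "go_domain")
    if (!all(need %in% names(ann)))
      stop("annotation TSV must have header columns: ",
           paste(need, collapse = ", "))
    if (is.null(ann$term_name)) ann$term_name <- NA_character_
    ann <- ann[, c("id", "go_id", "go_domain", "term_name")]
  }
  map <- c(P = "BP", F = "MF", C = "CC", BP = "BP", MF = "MF", CC = "CC",
           biological_process = "BP", molecular_function = "MF",
           cellular_component = "CC")
  dom <- map[ann$go_domain]
  if (anyNA(dom))
    stop("unrecognised GO domain value(s): ",
         paste(unique(ann$go_domain[is.na(dom)]), collapse = ", "))
  ann$go_domain <- unname(dom)
  ann
}

#' Choose the representative isoform and union GO sets for one gene
#'
#' The representative is the isoform with the longest protein (ties broken
#' by lexicographically smallest isoform id). GO tags retrieved by any
#' isoform, or keyed directly by the gene id, are unioned onto the gene.
#'
#' @param gene_record A list or one-row data frame with `gene_id`,
#'   `chromosome`, `start`, `end`, `strand` and optional `description`.
#' @param isoforms Data frame with columns `isoform_id`, `sequence` for this
#'   gene's isoforms (may have zero rows).
#' @param annotations Annotation data frame as from [read_annotations()].
#' @return A one-row data frame with list columns `go_bp`, `go_mf`, `go_cc`.
#' @export
select_representative <- function(gene_record, isoforms, annotations) {
  g <- as.list(gene_record)
  if (nrow(isoforms) > 0) {
    len <- nchar(isoforms$sequence)
    if (any(len == 0)) stop("zero-length protein for gene ", g$gene_id)
    ord <- order(-len, isoforms$isoform_id)
    rep_iso <- isoforms$isoform_id[ord[[1]]]
    rep_seq <- isoforms$sequence[ord[[1]]]
  } else {
    warning("gene ", g$gene_id,
            " has no isoform protein; excluded from homology analysis")
    rep_iso <- NA_character_
    rep_seq <- NA_character_
  }
  keys <- c(g$gene_id, isoforms$isoform_id)
  ann <- annotations[annotations$id %in% keys, , drop = FALSE]
  go_of <- function(dom) sort(unique(ann$go_id[ann$go_domain == dom]))
  out <- data.frame(
    gene_id = g$gene_id, chromosome = g$chromosome,
    start = as.integer(g$start), end = as.integer(g$end),
    strand = g$strand,
    representative_isoform = rep_iso,
    protein = rep_seq,
    protein_length = if (is.na(rep_seq)) 0L else nchar(rep_seq),
    description = if (is.null(g$description)) NA_character_ else g$description,
    stringsAsFactors = FALSE
  )
  out$go_bp <- list(go_of("BP"))
  out$go_mf <- list(go_of("MF"))
  out$go_cc <- list(go_of("CC"))
  out
}

#' Build an ordered gene catalog
#'
#' Sorts genes per chromosome by ascending start (ties: ascending end, then
#' gene id), optionally propagates GO-BP terms to their ancestors in a GO
#' DAG (root terms excluded), and computes the GO-BP scan substrate: the
#' per-chromosome order of GO-BP-carrying genes (`bp_order`), the universe
#' size `universe_N` and the per-term universe counts `term_K`.
#'
#' @param genes Data frame of genes as produced by [select_representative()]
#'   (one row per gene, list columns `go_bp`, `go_mf`, `go_cc`).
#' @param dag Optional `go_dag` from [read_obo()]; required when
#'   `propagate = TRUE`.
#' @param propagate Augment each gene's GO-BP set with all ancestors of its
#'   terms (excluding roots). Off by default: annotation pipelines usually
#'   ship already-augmented GO sets.
#' @param term_names Optional named character vector mapping GO ids to
#'   labels, used in enrichment reports.
#' @return An object of class `GeneCatalog`.
#' @export
build_catalog <- function(genes, dag = NULL, propagate = FALSE,
                          term_names = NULL) {
  if (nrow(genes) == 0) stop("empty gene catalog")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][[1]])
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (propagate && is.null(dag)) stop("propagate = TRUE requires a GO DAG")
  ord <- order(genes$chromosome, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  genes$go_bp <- lapply(genes$go_bp, function(x) sort(unique(as.character(x))))
  genes$go_mf <- lapply(genes$go_mf, function(x) sort(unique(as.character(x))))
  genes$go_cc <- lapply(genes$go_cc, function(x) sort(unique(as.character(x))))
  if (propagate) {
    genes$go_bp <- lapply(genes$go_bp, function(terms) {
      if (!length(terms)) return(terms)
      sort(unique(c(terms, go_ancestors(dag, terms, include_roots = FALSE))))
    })
  }
  has_bp <- lengths(genes$go_bp) > 0
  chroms <- sort(unique(genes$chromosome))
  bp_order <- lapply(setNames(chroms, chroms), function(ch)
    which(genes$chromosome == ch & has_bp))
  term_K <- table(unlist(genes$go_bp[has_bp]))
  term_K <- setNames(as.integer(term_K), names(term_K))
  if (!is.null(dag) && length(dag$names))
    term_names <- c(term_names, dag$names[setdiff(names(dag$names),
                                                  names(term_names))])
  structure(list(
    genes = genes,
    bp_order = bp_order,
    universe_N = sum(has_bp),
    term_K = term_K,
    term_names = term_names,
    propagated = propagate
  ), class = "GeneCatalog")
}

#' Read a genome into a gene catalog
#'
#' High-level reader tying together [read_gff3()], [read_protein_fasta()],
#' [read_annotations()] and optionally [read_obo()], applying the
#' longest-isoform representative rule and the GO-union rule per gene, and
#' building the ordered catalog with [build_catalog()].
#'
#' @param gff,fasta,annotations Paths to the three input files.
#' @param obo Optional path to a GO ontology in OBO format.
#' @inheritParams build_catalog
#' @return A `GeneCatalog`.
#' @export
read_genome <- function(gff, fasta, annotations, obo = NULL,
                        propagate = FALSE) {
  rec <- read_gff3(gff)
  prot <- read_protein_fasta(fasta)
  ann <- read_annotations(annotations)
  dag <- if (!is.null(obo)) read_obo(obo) else NULL
  tx <- rec$transcripts
  tx$sequence <- as.character(prot[match(tx$isoform_id, names(prot))])
  rows <- lapply(seq_len(nrow(rec$genes)), function(i) {
    g <- rec$genes[i, , drop = FALSE]
    iso <- tx[!is.na(tx$gene_id) & tx$gene_id == g$gene_id &
                !is.na(tx$sequence), c("isoform_id", "sequence"), drop = FALSE]
    select_representative(g, iso, ann)
  })
  genes <- do.call(rbind, rows)
  tn <- ann$term_name[!is.na(ann$term_name) & nzchar(ann$term_name)]
  names(tn) <- ann$go_id[!is.na(ann$term_name) & nzchar(ann$term_name)]
  tn <- tn[!duplicated(names(tn))]
  build_catalog(genes, dag = dag, propagate = propagate,
                term_names = if (length(tn)) tn else NULL)
}

#' Serialize a gene catalog to GFF3 + FASTA + annotation TSV
#'
#' Writes the catalog in the exact formats [read_genome()] consumes (one
#' mRNA per gene, named after the representative isoform), so that reading
#' the files back reconstructs the catalog.
#'
#' @param catalog A `GeneCatalog`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named character vector of the three file paths.
#' @export
write_catalog <- function(catalog, dir, prefix = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- catalog$genes
  iso_id <- ifelse(is.na(g$representative_isoform),
                   paste0(g$gene_id, ".t1"), g$representative_isoform)
  n <- nrow(g)
  # interleaved gene/mRNA records

  gr <- GenomicRanges::GRanges(
    rep(g$chromosome, each = 2),
    IRanges::IRanges(rep(g$start, each = 2), rep(g$end, each = 2)),
    strand = rep(g$strand, each = 2))
  gr$type <- rep(c("gene", "mRNA"), n)
  gr$ID <- as.vector(rbind(g$gene_id, iso_id))
  parent <- vector("list", 2L * n)
  parent[seq(2, 2 * n, by = 2)] <- as.list(g$gene_id)
  parent[seq(1, 2 * n, by = 2)] <- list(character(0))
  gr$Parent <- S4Vectors::SimpleList(parent)
  if (any(!is.na(g$description))) gr$description <-
    as.vector(rbind(g$description, NA_character_))
  paths <- c(gff = file.path(dir, paste0(prefix, ".gff3")),
             fasta = file.path(dir, paste0(prefix, "_proteins.fasta")),
             annotations = file.path(dir, paste0(prefix, "_annotations.tsv")))
  rtracklayer::export(gr, paths[["gff"]], format = "gff3")
  has_prot <- !is.na(g$protein)
  aa <- Biostrings::AAStringSet(g$protein[has_prot])
  names(aa) <- iso_id[has_prot]
  Biostrings::writeXStringSet(aa, paths[["fasta"]])
  ann <- do.call(rbind, lapply(seq_len(n), function(i) {
    terms <- c(g$go_bp[[i]], g$go_mf[[i]], g$go_cc[[i]])
    if (!length(terms)) return(NULL)
    data.frame(id = g$gene_id[[i]], go_id = terms,
               go_domain = rep(c("BP", "MF", "CC"),
                               c(length(g$go_bp[[i]]), length(g$go_mf[[i]]),
                                 length(g$go_cc[[i]]))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ann))
    ann <- data.frame(id = character(), go_id = character(),
                      go_domain = character())
  ann$term_name <- if (is.null(catalog$term_names)) NA_character_ else
    unname(catalog$term_names[ann$go_id])
  utils::write.table(ann, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  paths
}

#' @export
print.GeneCatalog <- function(x, ...) {
  cat("GeneCatalog:", nrow(x$genes), "genes on",
      length(x$bp_order), "chromosome(s)\n")
  cat("  GO-BP universe:", x$universe_N, "genes,",
      length(x$term_K), "distinct GO-BP terms\n")
  cat("  ancestor propagation:", if (x$propagated) "on" else "off", "\n")
  invisible(x)
}
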