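# Tandem-duplicate detection: all-vs-all local protein alignment within a
# window, stringency-preset filtering, single-linkage grouping and
# keep-first collapse.

# Karlin-Altschul constants for gapped BLOSUM62 (open 11, extend 1); used
# only for the E <= 10 recording threshold and reporting, never for tandem
# calls, which rest on identity/coverage alone.
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Tandem-duplicate stringency setting
#'
#' The four presets used for tandem-duplicate calling are
#' `setting_1` = (40% identity, ratio 0.4), `setting_2` = (70%, 0.7),
#' `setting_3` = (90%, 0.9) and `setting_4` = (98%, 0.98). The ratio
#' applies to both alignment-length/query-length and
#' alignment-length/subject-length. Lower thresholds call more pairs as
#' tandem duplicates, remove more genes before enrichment, and therefore
#' yield fewer cluster calls.
#'
#' @param preset Integer 1..4 selecting a preset, or `NULL` to supply
#'   custom thresholds.
#' @param min_identity_pct,min_ratio Custom thresholds (used when
#'   `preset` is `NULL`).
#' @return An object of class `TandemSetting`.
#' @export
tandem_setting <- function(preset = 2L, min_identity_pct = NULL,
                           min_ratio = NULL) {
  presets <- list(c(40, 0.4), c(70, 0.7), c(90, 0.9), c(98, 0.98))
  if (!is.null(preset)) {
    if (!preset %in% 1:4) stop("preset must be 1, 2, 3 or 4")
    min_identity_pct <- presets[[preset]][[1]]
    min_ratio <- presets[[preset]][[2]]
    name <- paste0("setting_", preset)
  } else {
    if (is.null(min_identity_pct) || is.null(min_ratio))
      stop("supply min_identity_pct and min_ratio when preset is NULL")
    name <- sprintf("custom_%g_%g", min_identity_pct, min_ratio)
  }
  structure(list(name = name, min_identity_pct = min_identity_pct,
                 min_ratio = min_ratio), class = "TandemSetting")
}

.check_protein <- function(seq, who) {
  if (is.na(seq) || !nzchar(seq)) stop("empty protein sequence for ", who)
  ok <- rownames(.blosum62())
  bad <- setdiff(strsplit(seq, "")[[1]], ok)
  if (length(bad))
    stop("non-amino-acid character(s) in protein of ", who, ": ",
         paste(unique(bad), collapse = ""))
}

#' Align protein pairs (Smith-Waterman, BLOSUM62, affine gaps)
#'
#' Gapped local alignment with BLOSUM62, gap open 11, gap extend 1.
#' Identity is matches over alignment columns including gap columns (the
#' BLAST tabular convention); gap-excluded lengths are recorded alongside.
#' One row per pair (the single best-scoring local alignment).
#'
#' @param proteins Named character vector (or [Biostrings::AAStringSet])
#'   of protein sequences keyed by gene id.
#' @param pairs Two-column matrix (or data frame) of gene-id pairs to
#'   align; default: all unordered pairs.
#' @param evalue_max Record only hits with E-value at or below this
#'   threshold (default 10).
#' @return A data frame of alignment hits, one row per recorded pair, with
#'   identity, length, ratio, score, bit score and E-value columns.
#' @export
align_pairs <- function(proteins, pairs = NULL, evalue_max = 10) {
  proteins <- setNames(as.character(proteins), names(proteins))
  for (id in names(proteins)) .check_protein(proteins[[id]], id)
  if (is.null(pairs)) {
    if (length(proteins) < 2) return(.empty_hits())
    pairs <- t(utils::combn(names(proteins), 2))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) return(.empty_hits())
  p <- Biostrings::AAStringSet(proteins[pairs[, 1]])
  s <- Biostrings::AAStringSet(proteins[pairs[, 2]])
  aln <- Biostrings::pairwiseAlignment(
    p, s, type = "local", substitutionMatrix = .blosum62(),
    gapOpening = 11, gapExtension = 1)
  q_len <- nchar(proteins[pairs[, 1]])
  s_len <- nchar(proteins[pairs[, 2]])
  align_len <- Biostrings::nchar(aln)
  nmatch <- Biostrings::nmatch(aln)
  nmism <- Biostrings::nmismatch(aln)
  ins <- Biostrings::insertion(aln)
  del <- Biostrings::deletion(aln)
  score <- Biostrings::score(aln)
  evalue <- .KA_K * q_len * s_len * exp(-.KA_LAMBDA * score)
  hits <- data.frame(
    query_id = pairs[, 1], subject_id = pairs[, 2],
    q_len = unname(q_len), s_len = unname(s_len),
    identity_pct = 100 * nmatch / align_len,
    align_len = align_len,
    align_len_nogap = nmatch + nmism,
    mismatches = nmism,
    gap_openings = S4Vectors::elementNROWS(ins) +
      S4Vectors::elementNROWS(del),
    q_start = Biostrings::start(Biostrings::pattern(aln)),
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln)),
    score = score,
    bit_score = (.KA_LAMBDA * score - log(.KA_K)) / log(2),
    evalue = evalue,
    stringsAsFactors = FALSE
  )
  hits$ratio_q <- hits$align_len / hits$q_len
  hits$ratio_s <- hits$align_len / hits$s_len
  hits$ratio_q_nogap <- hits$align_len_nogap / hits$q_len
  hits$ratio_s_nogap <- hits$align_len_nogap / hits$s_len
  hits[hits$evalue <= evalue_max, , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_len = integer(), s_len = integer(), identity_pct = double(),
             align_len = integer(), align_len_nogap = integer(),
             mismatches = integer(), gap_openings = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), score = double(), bit_score = double(),
             evalue = double(), ratio_q = double(), ratio_s = double(),
             ratio_q_nogap = double(), ratio_s_nogap = double(),
             stringsAsFactors = FALSE)
}

#' Align one protein pair
#'
#' @param protein_a,protein_b Protein sequences (character).
#' @param id_a,id_b Identifiers reported in the hit row.
#' @inheritParams align_pairs
#' @return A one-row (or zero-row, if E > `evalue_max`) hit data frame.
#' @export
align_pair <- function(protein_a, protein_b, id_a = "A", id_b = "B",
                       evalue_max = 10) {
  align_pairs(setNames(c(protein_a, protein_b), c(id_a, id_b)),
              pairs = cbind(id_a, id_b), evalue_max = evalue_max)
}

# Word length for the seed prescreen: largest k (<= 6) such that a pair
# meeting the setting's identity/coverage thresholds still shares an exact
# word with overwhelming probability (expected word count >= 20 under
# independent columns). The coverage requirement on both ratios forces at
# least min_ratio * max(q_len, s_len) alignment columns. k = 1 disables
# the prescreen.
seed_word_size <- function(setting, max_len) {
  m <- setting$min_identity_pct / 100
  L <- setting$min_ratio * max_len
  k <- 1L
  for (cand in 2:6) {
    if ((L - cand + 1) * m^cand >= 20) k <- cand else break
  }
  k
}

.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' All-vs-all alignment of the genes in a window
#'
#' Aligns every unordered pair of window genes that carry a protein. When
#' a stringency setting is supplied, pairs are pre-screened BLAST-style by
#' exact shared words: each pair's word length is chosen from its protein
#' lengths so that a pair meeting the setting's identity and coverage
#' thresholds seeds with overwhelming probability, and un-seeded pairs are
#' skipped without alignment. Pass `setting = NULL` (or a setting at 40%
#' identity, where the word length degenerates to 1) to align every pair
#' exhaustively.
#'
#' @param window_genes Data frame with columns `gene_id` and `protein`.
#' @param setting Optional [tandem_setting()] guiding the seed prescreen.
#' @inheritParams align_pairs
#' @return Hit data frame as from [align_pairs()].
#' @export
align_window <- function(window_genes, setting = NULL, evalue_max = 10) {
  g <- window_genes[!is.na(window_genes$protein), , drop = FALSE]
  if (nrow(g) < 2) return(.empty_hits())
  prot <- setNames(g$protein, g$gene_id)
  pairs <- t(utils::combn(g$gene_id, 2))
  if (!is.null(setting)) {
    len <- nchar(prot)
    pair_max <- pmax(len[pairs[, 1]], len[pairs[, 2]])
    k_pair <- vapply(pair_max, function(L) seed_word_size(setting, L), 0L)
    kmer_cache <- new.env(parent = emptyenv())
    kmers <- function(id, k) {
      key <- paste0(id, ".", k)
      if (is.null(kmer_cache[[key]]))
        kmer_cache[[key]] <- .kmer_set(prot[[id]], k)
      kmer_cache[[key]]
    }
    keep <- vapply(seq_len(nrow(pairs)), function(i) {
      k <- k_pair[[i]]
      k == 1L || any(kmers(pairs[i, 1], k) %in% kmers(pairs[i, 2], k))
    }, NA)
    pairs <- pairs[keep, , drop = FALSE]
  }
  align_pairs(prot, pairs = pairs, evalue_max = evalue_max)
}

#' Does a hit pass a tandem stringency setting?
#'
#' A pair is called tandem when identity and both coverage ratios
#' (alignment length over query length, and over subject length; gap
#' columns included) meet the setting's thresholds.
#'
#' @param hits Hit data frame from [align_pairs()].
#' @param setting A [tandem_setting()].
#' @return Logical vector along the rows of `hits`.
#' @export
passes_setting <- function(hits, setting) {
  hits$identity_pct >= setting$min_identity_pct &
    hits$ratio_q >= setting$min_ratio &
    hits$ratio_s >= setting$min_ratio
}

#' Single-linkage tandem groups within a window
#'
#' Connected components over window gene pairs whose hits pass the
#' stringency setting. Singleton genes are not returned. Each group's
#' representative is its first member by ascending genomic coordinate
#' (start, then end, then gene id).
#'
#' @param window_genes Data frame with columns `gene_id`, `start`, `end`,
#'   ordered or not.
#' @param hits Hit data frame restricted to (or a superset of) the window's
#'   pairs.
#' @param setting A [tandem_setting()].
#' @return List of groups, each a list with `members` (gene ids in
#'   coordinate order) and `representative`.
#' @export
tandem_groups <- function(window_genes, hits, setting) {
  ids <- window_genes$gene_id
  ord <- order(window_genes$start, window_genes$end, window_genes$gene_id)
  rank <- setNames(seq_along(ids), ids[ord])
  pass <- hits[passes_setting(hits, setting) &
                 hits$query_id %in% ids & hits$subject_id %in% ids,
               c("query_id", "subject_id"), drop = FALSE]
  if (nrow(pass) == 0) return(list())
  # union-find over window gene ids
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pass))) {
    a <- find(pass$query_id[[i]]); b <- find(pass$subject_id[[i]])
    if (a != b) parent[[a]] <- b
  }
  comp <- vapply(ids, find, "")
  grps <- split(ids, comp)
  grps <- grps[lengths(grps) >= 2]
  out <- lapply(grps, function(m) {
    m <- m[order(rank[m])]
    list(members = m, representative = m[[1]])
  })
  names(out) <- NULL
  out[order(vapply(out, function(g) rank[[g$representative]], 0))]
}

#' Collapse tandem groups to their first-by-coordinate representative
#'
#' Removes every non-representative member of each tandem group from the
#' window, preserving the original gene order. Idempotent.
#'
#' @param window_genes Data frame of window genes (any columns; must
#'   include `gene_id`, `start`, `end`).
#' @param groups Groups from [tandem_groups()] on the same window.
#' @return List with `retained` (data frame, original order) and `removed`
#'   (character vector of gene ids in coordinate order).
#' @export
collapse_tandems <- function(window_genes, groups) {
  removed <- unlist(lapply(groups, function(g)
    setdiff(g$members, g$representative)), use.names = FALSE)
  if (is.null(removed)) removed <- character()
  keep <- !(window_genes$gene_id %in% removed)
  rem <- window_genes[!keep, , drop = FALSE]
  rem <- rem[order(rem$start, rem$end, rem$gene_id), , drop = FALSE]
  list(retained = window_genes[keep, , drop = FALSE],
       removed = rem$gene_id)
}

# Table-1-style BLAST tabular columns for hit dumps.
.blast_columns <- c(
  "Query_id", "len_query", "Subject_id", "len_subject", "identity",
  "alignment_length", "mismatches", "gap_openings", "q_start", "q_end",
  "s_start", "s_end", "e-value", "bit_score", "len_algn_VS_len_query",
  "len_algn_VS_len_subj", "len_query_vs_len_subj",
  "len_algn_minus_gaps_vs_len_subj", "len_algn_minus_gaps_vs_len_query")

#' Write hits as a BLAST-tabular-style TSV
#'
#' @param hits Hit data frame from [align_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blast_tsv <- function(hits, path) {
  out <- data.frame(
    hits$query_id, hits$q_len, hits$subject_id, hits$s_len,
    round(hits$identity_pct, 2), hits$align_len, hits$mismatches,
    hits$gap_openings, hits$q_start, hits$q_end, hits$s_start, hits$s_end,
    signif(hits$evalue, 3), round(hits$bit_score, 1),
    round(hits$ratio_q, 4), round(hits$ratio_s, 4),
    round(hits$q_len / hits$s_len, 4),
    round(hits$ratio_s_nogap, 4), round(hits$ratio_q_nogap, 4),
    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- .blast_columns
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read precomputed alignment hits (external-aligner mode)
#'
#' Accepts either the 19-column TSV written by [write_blast_tsv()]
#' (recognised by its header) or a headerless standard 12-column BLAST
#' `outfmt 6` table, in which case query/subject lengths must be supplied
#' to compute coverage ratios. Identity and length fields are passed
#' through bit-exact.
#'
#' @param path Input TSV.
#' @param seq_lengths Named integer vector of protein lengths, required for
#'   12-column input.
#' @return Hit data frame in the layout of [align_pairs()].
#' @export
read_blast_tsv <- function(path, seq_lengths = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "Query_id\t")) {
    x <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    hits <- data.frame(
      query_id = x$Query_id, subject_id = x$Subject_id,
      q_len = x$len_query, s_len = x$len_subject,
      identity_pct = x$identity, align_len = x$alignment_length,
      align_len_nogap = NA_integer_, mismatches = x$mismatches,
      gap_openings = x$gap_openings, q_start = x$q_start, q_end = x$q_end,
      s_start = x$s_start, s_end = x$s_end, score = NA_real_,
      bit_score = x$bit_score, evalue = x$`e-value`,
      ratio_q = x$len_algn_VS_len_query, ratio_s = x$len_algn_VS_len_subj,
      ratio_q_nogap = x$len_algn_minus_gaps_vs_len_query,
      ratio_s_nogap = x$len_algn_minus_gaps_vs_len_subj,
      stringsAsFactors = FALSE)
  } else {
    x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(x) < 12) stop("expected 12-column BLAST outfmt 6 input")
    if (is.null(seq_lengths))
      stop("seq_lengths is required for 12-column outfmt 6 input")
    q_len <- unname(seq_lengths[x[[1]]])
    s_len <- unname(seq_lengths[x[[2]]])
    if (anyNA(q_len) || anyNA(s_len))
      stop("sequence length missing for some hit ids")
    hits <- data.frame(
      query_id = x[[1]], subject_id = x[[2]], q_len = q_len, s_len = s_len,
      identity_pct = x[[3]], align_len = x[[4]],
      align_len_nogap = NA_integer_, mismatches = x[[5]],
      gap_openings = x[[6]], q_start = x[[7]], q_end = x[[8]],
      s_start = x[[9]], s_end = x[[10]], score = NA_real_,
      bit_score = x[[12]], evalue = x[[11]],
      ratio_q = x[[4]] / q_len, ratio_s = x[[4]] / s_len,
      ratio_q_nogap = NA_real_, ratio_s_nogap = NA_real_,
      stringsAsFactors = FALSE)
  }
  hits
}
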