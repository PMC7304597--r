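# Seeded synthetic genomes with planted functional clusters, tandem arrays
# at controlled protein identity, background GO noise and unannotated
# genes, plus the matching ground-truth table.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Random protein sequence
#'
#' Residues drawn i.i.d. uniformly over the 20 standard amino acids, so
#' that unrelated synthetic proteins are non-homologous by construction:
#' their local-alignment identity stays far below the 40% setting_1
#' threshold with overwhelming probability.
#'
#' @param n Protein length (aa).
#' @return A character scalar.
#' @export
random_protein <- function(n)
  paste(sample(.AA20, n, replace = TRUE), collapse = "")

#' Mutate a protein to a target identity
#'
#' Per-site substitution with probability `1 - target_identity`; the
#' replacement is drawn uniformly from the 19 alternative residues. No
#' indels.
#'
#' @param seq Protein sequence (character).
#' @param target_identity Fraction in (0, 1].
#' @return The mutated sequence.
#' @export
mutate_protein <- function(seq, target_identity) {
  stopifnot(target_identity > 0, target_identity <= 1)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < (1 - target_identity)
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(.AA20, a), 1L), "")
  paste(chars, collapse = "")
}

#' Synthetic genome configuration
#'
#' Defaults emulate the annotation structure of a well-annotated plant
#' genome at the scale used for validation: 38% of genes lack GO-BP (about
#' half of those lack any GO tag), planted clusters of 3-10 genes (the
#' size range reported for plant functional clusters; default 4-6), and
#' tandem arrays at 95% target protein identity.
#'
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param gene_length_bp,intergenic_bp Sampling ranges (min, max) in bp.
#' @param frac_no_go_bp Fraction of genes lacking GO-BP annotation.
#' @param frac_no_go_any Fraction of genes lacking any GO tag (subset of
#'   `frac_no_go_bp`).
#' @param go_vocab_size Number of background GO-BP terms.
#' @param background_terms_per_gene Range of GO-BP terms drawn i.i.d. from
#'   the vocabulary for each annotated gene, so no background term
#'   clusters positionally beyond chance.
#' @param n_planted_clusters,planted_cluster_size Planted functional
#'   clusters: consecutive, mutually non-homologous genes sharing one
#'   reserved GO-BP term.
#' @param n_tandem_arrays,tandem_copies,tandem_identity Planted tandem
#'   arrays: consecutive copies of one protein mutated to the target
#'   identity, sharing one reserved GO-BP term.
#' @param protein_length_aa Protein length range (aa).
#' @param seed Integer seed; the same seed yields an identical genome.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_chromosomes = 5L, genes_per_chromosome = 600L,
                       gene_length_bp = c(1000L, 5000L),
                       intergenic_bp = c(2000L, 20000L),
                       frac_no_go_bp = 0.38, frac_no_go_any = 0.20,
                       go_vocab_size = 500L,
                       background_terms_per_gene = c(1L, 4L),
                       n_planted_clusters = 15L,
                       planted_cluster_size = c(4L, 6L),
                       n_tandem_arrays = 5L, tandem_copies = c(3L, 6L),
                       tandem_identity = 0.95,
                       protein_length_aa = c(150L, 400L), seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              gene_length_bp = as.integer(gene_length_bp),
              intergenic_bp = as.integer(intergenic_bp),
              frac_no_go_bp = frac_no_go_bp,
              frac_no_go_any = frac_no_go_any,
              go_vocab_size = as.integer(go_vocab_size),
              background_terms_per_gene =
                as.integer(background_terms_per_gene),
              n_planted_clusters = as.integer(n_planted_clusters),
              planted_cluster_size = as.integer(planted_cluster_size),
              n_tandem_arrays = as.integer(n_tandem_arrays),
              tandem_copies = as.integer(tandem_copies),
              tandem_identity = tandem_identity,
              protein_length_aa = as.integer(protein_length_aa),
              seed = as.integer(seed))
  stopifnot(cfg$frac_no_go_bp >= 0, cfg$frac_no_go_bp <= 1,
            cfg$frac_no_go_any >= 0,
            cfg$frac_no_go_any <= cfg$frac_no_go_bp,
            cfg$tandem_identity > 0, cfg$tandem_identity <= 1)
  for (r in c("gene_length_bp", "intergenic_bp",
              "background_terms_per_gene", "planted_cluster_size",
              "tandem_copies", "protein_length_aa"))
    if (length(cfg[[r]]) != 2 || cfg[[r]][[1]] > cfg[[r]][[2]])
      stop(r, " must be a (min, max) range")
  structure(cfg, class = "SimConfig")
}

.sample_range <- function(r, n = 1L) {
  if (r[[1]] == r[[2]]) rep(r[[1]], n) else
    sample(seq(r[[1]], r[[2]]), n, replace = TRUE)
}

# Reserve non-overlapping runs of consecutive gene slots, at least 5 slots
# apart, for planted features.
.reserve_runs <- function(n_chrom, n_per_chrom, sizes) {
  taken <- lapply(seq_len(n_chrom), function(i) logical(n_per_chrom))
  runs <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    s <- sizes[[i]]
    ok <- FALSE
    for (try in seq_len(2000L)) {
      ch <- sample.int(n_chrom, 1L)
      if (n_per_chrom < s) next
      at <- sample.int(n_per_chrom - s + 1L, 1L)
      guard <- max(1L, at - 5L):min(n_per_chrom, at + s + 4L)
      if (!any(taken[[ch]][guard])) {
        taken[[ch]][at:(at + s - 1L)] <- TRUE
        runs[[i]] <- list(chromosome = ch, slots = at:(at + s - 1L))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible config: cannot place planted features ",
                  "(too many/large for the genome)")
  }
  runs
}

#' Generate a synthetic genome with planted ground truth
#'
#' Builds a seeded multi-chromosome gene catalog with realistic intergenic
#' gaps, background GO-BP noise drawn i.i.d. from a term vocabulary, a
#' configurable fraction of genes lacking GO (BP or any domain), planted
#' functional clusters (consecutive, mutually non-homologous genes sharing
#' one reserved GO-BP term) and planted tandem arrays (consecutive mutated
#' copies of one protein sharing a reserved term). Optionally writes the
#' GFF3 + protein FASTA + annotation TSV files and the truth table.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, the catalog files and
#'   `truth.tsv` are written there.
#' @return List with `catalog` (a `GeneCatalog`), `truth` (data frame:
#'   `type`, `cluster_id`, `chromosome`, `gene_ids` (comma-separated),
#'   `go_id`, `target_identity`, `realized_identity`) and `files` (paths,
#'   when `dir` was given).
#' @export
simulate_genome <- function(config = sim_config(), dir = NULL) {
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  npc <- config$genes_per_chromosome
  chrom_names <- sprintf("chr%02d", seq_len(n_chrom))

  planted_sizes <- .sample_range(config$planted_cluster_size,
                                 config$n_planted_clusters)
  tandem_sizes <- .sample_range(config$tandem_copies,
                                config$n_tandem_arrays)
  runs <- .reserve_runs(n_chrom, npc, c(planted_sizes, tandem_sizes))
  planted_runs <- runs[seq_len(config$n_planted_clusters)]
  tandem_runs <- runs[config$n_planted_clusters + seq_len(config$n_tandem_arrays)]

  bp_vocab <- sprintf("GO:1%06d", seq_len(config$go_vocab_size))
  mf_vocab <- sprintf("GO:4%06d", seq_len(200L))
  cc_vocab <- sprintf("GO:5%06d", seq_len(100L))
  planted_terms <- sprintf("GO:2%06d", seq_len(config$n_planted_clusters))
  tandem_terms <- sprintf("GO:3%06d", seq_len(config$n_tandem_arrays))

  # per-slot role bookkeeping
  role <- lapply(seq_len(n_chrom), function(i)
    integer(npc))  # 0 background; >0 planted idx; <0 tandem idx
  for (i in seq_along(planted_runs))
    role[[planted_runs[[i]]$chromosome]][planted_runs[[i]]$slots] <- i
  for (i in seq_along(tandem_runs))
    role[[tandem_runs[[i]]$chromosome]][tandem_runs[[i]]$slots] <- -i
  tandem_base <- lapply(tandem_sizes, function(s)
    random_protein(.sample_range(config$protein_length_aa)))
  # each copy diverges from the common ancestor by half the target
  # divergence (star topology), so PAIRWISE identity between copies
  # realizes the configured tandem_identity
  copy_identity <- 1 - (1 - config$tandem_identity) / 2

  all_genes <- vector("list", n_chrom)
  truth_rows <- list()
  tandem_prot <- lapply(seq_along(tandem_runs), function(i)
    vapply(seq_len(tandem_sizes[[i]]), function(j)
      mutate_protein(tandem_base[[i]], copy_identity), ""))

  for (ch in seq_len(n_chrom)) {
    lens <- .sample_range(config$gene_length_bp, npc)
    gaps <- .sample_range(config$intergenic_bp, npc)
    starts <- cumsum(gaps + c(0L, lens[-npc]))
    ends <- starts + lens - 1L
    ids <- sprintf("SYNG%02dG%04d", ch, seq_len(npc) * 10L)
    strand <- sample(c("+", "-"), npc, replace = TRUE)
    u <- runif(npc)
    prot <- character(npc)
    go_bp <- vector("list", npc)
    go_mf <- vector("list", npc)
    go_cc <- vector("list", npc)
    tandem_pos <- integer(length(tandem_runs))
    for (i in seq_len(npc)) {
      r <- role[[ch]][[i]]
      if (r < 0) {  # tandem array member
        tandem_pos[[-r]] <- tandem_pos[[-r]] + 1L
        prot[[i]] <- tandem_prot[[-r]][[tandem_pos[[-r]]]]
        go_bp[[i]] <- tandem_terms[[-r]]
        next
      }
      prot[[i]] <- random_protein(.sample_range(config$protein_length_aa))
      if (r > 0) {  # planted cluster member
        go_bp[[i]] <- planted_terms[[r]]
        next
      }
      if (u[[i]] < config$frac_no_go_any) next
      if (u[[i]] < config$frac_no_go_bp) {
        go_mf[[i]] <- sample(mf_vocab, sample.int(2L, 1L))
        if (runif(1) < 0.5) go_cc[[i]] <- sample(cc_vocab, 1L)
        next
      }
      nt <- .sample_range(config$background_terms_per_gene)
      go_bp[[i]] <- unique(sample(bp_vocab, nt, replace = TRUE))
      if (runif(1) < 0.5) go_mf[[i]] <- sample(mf_vocab, 1L)
      if (runif(1) < 0.3) go_cc[[i]] <- sample(cc_vocab, 1L)
    }
    g <- data.frame(gene_id = ids, chromosome = chrom_names[[ch]],
                    start = starts, end = ends, strand = strand,
                    representative_isoform = paste0(ids, ".1"),
                    protein = prot, protein_length = nchar(prot),
                    description = NA_character_, stringsAsFactors = FALSE)
    g$go_bp <- go_bp
    g$go_mf <- go_mf
    g$go_cc <- go_cc
    all_genes[[ch]] <- g
  }
  genes <- do.call(rbind, all_genes)

  hamming_identity <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x == y)
  }
  truth <- list()
  for (i in seq_along(planted_runs)) {
    run <- planted_runs[[i]]
    ids <- all_genes[[run$chromosome]]$gene_id[run$slots]
    truth[[length(truth) + 1L]] <- data.frame(
      type = "planted_cluster", cluster_id = i,
      chromosome = chrom_names[[run$chromosome]],
      gene_ids = paste(ids, collapse = ","), go_id = planted_terms[[i]],
      target_identity = NA_real_, realized_identity = NA_real_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(tandem_runs)) {
    run <- tandem_runs[[i]]
    ids <- all_genes[[run$chromosome]]$gene_id[run$slots]
    prots <- tandem_prot[[i]]
    pid <- utils::combn(length(prots), 2, function(p)
      hamming_identity(prots[[p[1]]], prots[[p[2]]]))
    truth[[length(truth) + 1L]] <- data.frame(
      type = "tandem_array", cluster_id = i,
      chromosome = chrom_names[[run$chromosome]],
      gene_ids = paste(ids, collapse = ","), go_id = tandem_terms[[i]],
      target_identity = config$tandem_identity,
      realized_identity = round(mean(pid), 4), stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), cluster_id = integer(),
               chromosome = character(), gene_ids = character(),
               go_id = character(), target_identity = double(),
               realized_identity = double(), stringsAsFactors = FALSE)

  term_names <- setNames(
    c(sprintf("synthetic process %d", seq_along(bp_vocab)),
      sprintf("planted cluster process %d", seq_along(planted_terms)),
      sprintf("tandem array process %d", seq_along(tandem_terms)),
      sprintf("synthetic function %d", seq_along(mf_vocab)),
      sprintf("synthetic component %d", seq_along(cc_vocab))),
    c(bp_vocab, planted_terms, tandem_terms, mf_vocab, cc_vocab))
  catalog <- build_catalog(genes, term_names = term_names)

  files <- NULL
  if (!is.null(dir)) {
    files <- write_catalog(catalog, dir, prefix = "synthetic")
    truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, truth = truth_path)
  }
  list(catalog = catalog, truth = truth, files = files)
}

#' Shuffle GO-BP label sets across genes (null model)
#'
#' Permutes the assignment of complete GO-BP sets across the
#' GO-BP-carrying genes. Term universe counts and the universe size are
#' conserved; positional signal is destroyed, making the shuffled catalog
#' a null model for false-positive calibration.
#'
#' @param catalog A `GeneCatalog`.
#' @return The catalog with permuted GO-BP sets.
#' @export
shuffle_go_labels <- function(catalog) {
  idx <- which(lengths(catalog$genes$go_bp) > 0)
  catalog$genes$go_bp[idx] <- catalog$genes$go_bp[idx[sample.int(length(idx))]]
  catalog
}

#' Score planted-cluster recovery
#'
#' A planted cluster counts as recovered when some call's span contains at
#' least `min_members` of its member genes and the call's top GO term is
#' the planted term.
#'
#' @param calls Calls (an `FNTDCCallSet` or list).
#' @param truth Truth table from [simulate_genome()].
#' @param catalog The `GeneCatalog` (for member coordinates).
#' @param min_members Minimum planted members inside the call span.
#' @return List with `n_planted`, `n_recovered` and `per_cluster` (data
#'   frame: `cluster_id`, `go_id`, `recovered`, `call_ordinal`).
#' @export
evaluate_recovery <- function(calls, truth, catalog, min_members = 3L) {
  calls <- .calls_of(calls)
  planted <- truth[truth$type == "planted_cluster", , drop = FALSE]
  res <- lapply(seq_len(nrow(planted)), function(i) {
    ids <- strsplit(planted$gene_ids[[i]], ",")[[1]]
    g <- catalog$genes[match(ids, catalog$genes$gene_id), , drop = FALSE]
    hit <- NA_integer_
    for (x in calls) {
      if (x$top_go != planted$go_id[[i]]) next
      inside <- x$chromosome == g$chromosome & g$start >= x$span_bp[[1]] &
        g$end <= x$span_bp[[2]]
      if (sum(inside) >= min_members) { hit <- x$ordinal; break }
    }
    data.frame(cluster_id = planted$cluster_id[[i]],
               go_id = planted$go_id[[i]], recovered = !is.na(hit),
               call_ordinal = hit, stringsAsFactors = FALSE)
  })
  per <- if (length(res)) do.call(rbind, res) else
    data.frame(cluster_id = integer(), go_id = character(),
               recovered = logical(), call_ordinal = integer())
  list(n_planted = nrow(per), n_recovered = sum(per$recovered),
       per_cluster = per)
}
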