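# Fixtures are built in code at test time; nothing binary is stored.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# A bare gene table row in the layout build_catalog() expects.
gene_row <- function(gene_id, chromosome = "chr1", start = 1L,
                     end = start + 999L, strand = "+", protein = NA,
                     go_bp = character(), go_mf = character(),
                     go_cc = character()) {
  g <- data.frame(gene_id = gene_id, chromosome = chromosome,
                  start = as.integer(start), end = as.integer(end),
                  strand = strand,
                  representative_isoform = paste0(gene_id, ".1"),
                  protein = protein,
                  protein_length = if (is.na(protein)) 0L else
                    nchar(protein),
                  description = NA_character_, stringsAsFactors = FALSE)
  g$go_bp <- list(go_bp); g$go_mf <- list(go_mf); g$go_cc <- list(go_cc)
  g
}

# Catalog of n equally spaced genes on one chromosome; go_bp is a list of
# per-gene GO-BP sets (recycled NULL = empty).
toy_catalog <- function(go_bp, proteins = NULL, chromosome = "chr1") {
  n <- length(go_bp)
  rows <- lapply(seq_len(n), function(i)
    gene_row(sprintf("G%03d", i), chromosome = chromosome,
             start = i * 10000L, end = i * 10000L + 2000L,
             protein = if (is.null(proteins)) NA else proteins[[i]],
             go_bp = go_bp[[i]]))
  build_catalog(do.call(rbind, rows))
}

# Deterministic random protein without touching the caller's RNG stream.
fixed_protein <- function(n, seed) {
  withr::with_seed(seed, paste(sample(AA20, n, replace = TRUE),
                               collapse = ""))
}

# A tiny hand-written three-file genome for parser tests.
write_tiny_genome <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "tiny.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t3000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1000\t3000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\tmRNA\t1000\t2500\t.\t+\t.\tID=gA.2;Parent=gA",
    "chr1\tsrc\tgene\t5000\t7000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t5000\t7000\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr2\tsrc\tgene\t100\t900\t.\t+\t.\tID=gC",
    "chr2\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=gC.1;Parent=gC"), gff)
  fasta <- file.path(dir, "tiny.fasta")
  writeLines(c(
    ">gA.1 hypothetical protein",
    "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR",
    ">gA.2",
    "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
    ">gB.1",
    "MSDNGPQNQRNAPRITFGGPSDSTGSNQNGERSGARSKQRRPQGLPNNTASWFTALTQHGKEDL",
    ">gC.1",
    "MAGWNAYIDNLMADGTCQDAAIVGYKDSPSVWAAVPGKTFVNITPAEVGVLVGKDRSSFYVNGLTLGGQKCSVIRD"),
    fasta)
  ann <- file.path(dir, "tiny_annotations.tsv")
  writeLines(c(
    "id\tgo_id\tgo_domain\tterm_name",
    "gA.1\tGO:0006355\tBP\tregulation of transcription",
    "gA.2\tGO:0009058\tBP\tbiosynthetic process",
    "gA\tGO:0003677\tMF\tDNA binding",
    "gB\tGO:0009058\tBP\tbiosynthetic process",
    "gC.1\tGO:0005975\tBP\tcarbohydrate metabolic process"), ann)
  c(gff = gff, fasta = fasta, annotations = ann)
}

# Matching GAF 2.1 content for the same annotations (gene/isoform keyed).
write_tiny_gaf <- function(path) {
  row <- function(id, go, aspect)
    paste(c("DB", id, id, "", go, "REF", "IEA", "", aspect, "", "",
            "protein", "taxon:0", "20200101", "SRC"), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               row("gA.1", "GO:0006355", "P"),
               row("gA.2", "GO:0009058", "P"),
               row("gA", "GO:0003677", "F"),
               row("gB", "GO:0009058", "P"),
               row("gC.1", "GO:0005975", "P")), path)
  path
}

write_tiny_obo <- function(path, cyclic = FALSE) {
  stanza <- function(id, name, isa = NULL, part_of = NULL) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      if (!is.null(isa)) paste0("is_a: ", isa, " ! parent"),
      if (!is.null(part_of)) paste0("relationship: part_of ", part_of), "")
  }
  lines <- c("format-version: 1.2", "",
             stanza("GO:0008150", "biological_process"),
             stanza("GO:0009058", "biosynthetic process",
                    isa = "GO:0008150"),
             stanza("GO:0006355", "regulation of transcription",
                    isa = "GO:0008150"),
             stanza("GO:0044249", "cellular biosynthetic process",
                    isa = "GO:0009058",
                    part_of = if (cyclic) "GO:0099999"),
             stanza("GO:0099999", "leaf process",
                    isa = "GO:0044249"))
  writeLines(lines, path)
  path
}

# Independent brute-force oracle: fraction of all C(N, n) windows holding
# at least k of the K term genes, by explicit subset enumeration.
enum_upper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}
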