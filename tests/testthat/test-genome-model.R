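test_that("GFF3 genes and transcripts parse with coordinates preserved", {
  files <- write_tiny_genome(withr::local_tempdir())
  rec <- read_gff3(files[["gff"]])
  expect_equal(nrow(rec$genes), 3)
  gA <- rec$genes[rec$genes$gene_id == "gA", ]
  expect_equal(c(gA$start, gA$end), c(1000, 3000))
  expect_equal(gA$strand, "+")
  expect_setequal(rec$transcripts$isoform_id[rec$transcripts$gene_id == "gA"],
                  c("gA.1", "gA.2"))
})

test_that("malformed GFF3 lines are rejected with the line number", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t2000\t1000\t.\t+\t.\tID=g1"), bad)
  expect_error(read_gff3(bad), "line 2.*end.*start")
  writeLines(c("chr1\tsrc\tgene\t1000", ""), bad)
  expect_error(read_gff3(bad), "line 1")
  ok_gene_bad_parent <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=t1;Parent=nope"),
             ok_gene_bad_parent)
  expect_error(read_gff3(ok_gene_bad_parent), "Parent")
})

test_that("representative isoform is the longest protein, GO sets union", {
  g <- list(gene_id = "g1", chromosome = "chr1", start = 1, end = 10,
            strand = "+")
  iso <- data.frame(isoform_id = c("g1.1", "g1.2"),
                    sequence = c(strrep("A", 200), strrep("M", 350)),
                    stringsAsFactors = FALSE)
  ann <- data.frame(id = c("g1.1", "g1.2"), go_id = c("GO:A", "GO:B"),
                    go_domain = "BP", term_name = NA,
                    stringsAsFactors = FALSE)
  out <- select_representative(g, iso, ann)
  expect_equal(out$representative_isoform, "g1.2")
  expect_equal(out$protein_length, 350L)
  expect_setequal(out$go_bp[[1]], c("GO:A", "GO:B"))

  # tie on length -> lexicographically smallest isoform id
  iso2 <- data.frame(isoform_id = c("g1.b", "g1.a"),
                     sequence = c(strrep("C", 300), strrep("D", 300)),
                     stringsAsFactors = FALSE)
  expect_equal(select_representative(g, iso2, ann)$representative_isoform,
               "g1.a")

  # no isoform protein: retained with empty protein, warning
  expect_warning(out0 <- select_representative(g, iso[0, ], ann),
                 "no isoform")
  expect_true(is.na(out0$protein))
  expect_equal(out0$protein_length, 0L)
})

test_that("catalog universe and term counts are order-invariant", {
  rows <- rbind(
    gene_row("g1", start = 100, go_bp = c("GO:X", "GO:Y")),
    gene_row("g2", start = 200, go_bp = "GO:X"),
    gene_row("g3", start = 300),
    gene_row("g4", start = 400, go_bp = "GO:X", go_mf = "GO:M"),
    gene_row("g5", chromosome = "chr2", start = 50, go_bp = "GO:Y"),
    gene_row("g6", chromosome = "chr2", start = 60))
  cat1 <- build_catalog(rows)
  expect_equal(cat1$universe_N, 4)
  expect_equal(unname(cat1$term_K[c("GO:X", "GO:Y")]), c(3L, 2L))
  expect_equal(lengths(cat1$bp_order), c(chr1 = 3L, chr2 = 1L))
  # shuffled input rows give an identical catalog
  cat2 <- build_catalog(rows[c(4, 2, 6, 1, 5, 3), ])
  expect_equal(cat2, cat1)
  # duplicate ids and empty catalogs are rejected
  expect_error(build_catalog(rbind(rows, rows[1, ])), "duplicate")
  expect_error(build_catalog(rows[0, ]), "empty")
})

test_that("ancestor propagation unions genes up the DAG, roots excluded", {
  obo <- write_tiny_obo(withr::local_tempfile(fileext = ".obo"))
  dag <- read_obo(obo)
  # child term on two genes, parent on one distinct gene -> K(parent) = 3
  rows <- rbind(
    gene_row("g1", start = 100, go_bp = "GO:0044249"),
    gene_row("g2", start = 200, go_bp = "GO:0044249"),
    gene_row("g3", start = 300, go_bp = "GO:0009058"))
  catp <- build_catalog(rows, dag = dag, propagate = TRUE)
  expect_equal(unname(catp$term_K["GO:0009058"]), 3L)
  expect_equal(unname(catp$term_K["GO:0044249"]), 2L)
  # the root GO:0008150 never enters the term universe
  expect_false("GO:0008150" %in% names(catp$term_K))
  # propagation is monotone along every ancestor chain
  for (t in names(catp$term_K)) {
    for (anc in go_ancestors(dag, t, include_roots = FALSE))
      expect_gte(catp$term_K[[anc]], catp$term_K[[t]])
  }
  # off by default
  cat0 <- build_catalog(rows)
  expect_equal(unname(cat0$term_K["GO:0009058"]), 1L)
})

test_that("OBO reader rejects cycles and keeps names", {
  dag <- read_obo(write_tiny_obo(withr::local_tempfile(fileext = ".obo")))
  expect_equal(unname(dag$names["GO:0009058"]), "biosynthetic process")
  expect_setequal(go_ancestors(dag, "GO:0099999"),
                  c("GO:0044249", "GO:0009058", "GO:0008150"))
  cyc <- write_tiny_obo(withr::local_tempfile(fileext = ".obo"),
                        cyclic = TRUE)
  expect_error(read_obo(cyc), "cycle")
})

test_that("TSV and GAF annotation readers agree", {
  files <- write_tiny_genome(withr::local_tempdir())
  tsv <- read_annotations(files[["annotations"]])
  gaf <- read_annotations(write_tiny_gaf(withr::local_tempfile()))
  key <- function(x) x[order(x$id, x$go_id), c("id", "go_id", "go_domain")]
  expect_equal(key(gaf), key(tsv), ignore_attr = TRUE)
})

test_that("read_genome applies representative and union rules end to end", {
  files <- write_tiny_genome(withr::local_tempdir())
  cat <- read_genome(files[["gff"]], files[["fasta"]],
                     files[["annotations"]])
  gA <- cat$genes[cat$genes$gene_id == "gA", ]
  expect_equal(gA$representative_isoform, "gA.1")  # longer isoform
  # GO union across both isoforms and the gene-keyed MF row
  expect_setequal(gA$go_bp[[1]], c("GO:0006355", "GO:0009058"))
  expect_setequal(gA$go_mf[[1]], "GO:0003677")
  expect_equal(cat$universe_N, 3)
  expect_equal(unname(cat$term_K["GO:0009058"]), 2L)
  expect_equal(unname(cat$term_names["GO:0005975"]),
               "carbohydrate metabolic process")
})

test_that("catalog serialization round-trips", {
  sim <- simulate_genome(sim_config(n_chromosomes = 2,
                                    genes_per_chromosome = 40,
                                    n_planted_clusters = 1,
                                    n_tandem_arrays = 1, seed = 11))
  dir <- withr::local_tempdir()
  expect_no_warning(paths <- write_catalog(sim$catalog, dir))
  expect_no_warning(back <- read_genome(paths[["gff"]], paths[["fasta"]],
                                        paths[["annotations"]]))
  expect_equal(back$genes$gene_id, sim$catalog$genes$gene_id)
  expect_equal(back$genes$start, sim$catalog$genes$start)
  expect_equal(back$genes$protein, sim$catalog$genes$protein)
  expect_equal(back$genes$go_bp, sim$catalog$genes$go_bp)
  expect_equal(back$bp_order, sim$catalog$bp_order)
  expect_equal(back$universe_N, sim$catalog$universe_N)
  expect_equal(back$term_K, sim$catalog$term_K)
})
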