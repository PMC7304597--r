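test_that("identical and self alignments give 100% identity, full ratios", {
  p <- fixed_protein(300, seed = 1)
  h <- align_pair(p, p)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$align_len, 300L)
  expect_equal(h$ratio_q, 1)
  expect_equal(h$ratio_s, 1)
  expect_equal(h$gap_openings, 0L)
  # symmetric in identity and lengths
  a <- fixed_protein(250, seed = 2); b <- fixed_protein(300, seed = 3)
  hab <- align_pair(a, b); hba <- align_pair(b, a)
  if (nrow(hab) && nrow(hba)) {
    expect_equal(hab$identity_pct, hba$identity_pct)
    expect_equal(hab$align_len, hba$align_len)
  }
  expect_error(align_pair("", p), "empty")
  expect_error(align_pair("MKT9", p), "non-amino-acid")
})

test_that("aligner identity matches the substitution-mask column oracle", {
  # substitutions away from the termini so the local alignment spans the
  # full sequence and the identity equals the direct column count
  base <- fixed_protein(300, seed = 10)
  ch <- strsplit(base, "")[[1]]
  pos <- withr::with_seed(10, sample(4:297, 60))
  ch[pos] <- withr::with_seed(11, vapply(ch[pos], function(a)
    sample(setdiff(AA20, a), 1), ""))
  h <- align_pair(base, paste(ch, collapse = ""))
  expect_equal(h$identity_pct, 100 * (300 - 60) / 300)
  expect_equal(h$align_len, 300L)
  # heavier mask: terminal trimming allowed, identity still within a point
  pos2 <- withr::with_seed(12, sample(300, 120))
  ch2 <- strsplit(base, "")[[1]]
  ch2[pos2] <- withr::with_seed(13, vapply(ch2[pos2], function(a)
    sample(setdiff(AA20, a), 1), ""))
  h2 <- align_pair(base, paste(ch2, collapse = ""))
  expect_lt(abs(h2$identity_pct - 60), 1)
})

test_that("stringency presets filter hits as documented", {
  s <- lapply(1:4, tandem_setting)
  expect_equal(vapply(s, `[[`, 0, "min_identity_pct"), c(40, 70, 90, 98))
  expect_equal(vapply(s, `[[`, 0, "min_ratio"), c(0.4, 0.7, 0.9, 0.98))
  hit <- function(id, rq, rs) data.frame(identity_pct = id, ratio_q = rq,
                                         ratio_s = rs)
  # 75% identity, high coverage: passes settings 1-2 only
  expect_equal(vapply(s, function(x)
    passes_setting(hit(75, 0.95, 0.92), x), NA), c(TRUE, TRUE, FALSE, FALSE))
  # perfect hit passes everything
  expect_true(all(vapply(s, function(x)
    passes_setting(hit(100, 1, 1), x), NA)))
  # high identity, low query coverage: only setting_1
  expect_equal(vapply(s, function(x)
    passes_setting(hit(95, 0.5, 1), x), NA), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("passing a stricter preset implies passing every looser one", {
  hits <- withr::with_seed(5, data.frame(
    identity_pct = runif(200, 0, 100),
    ratio_q = runif(200, 0.2, 1.1),
    ratio_s = runif(200, 0.2, 1.1)))
  pass <- vapply(1:4, function(i)
    passes_setting(hits, tandem_setting(i)), logical(200))
  # columns ordered loose -> strict by construction of the presets
  for (i in 2:4) expect_true(all(pass[, i] <= pass[, i - 1]))
})

test_that("tandem groups are single-linkage with keep-first collapse", {
  genes <- data.frame(gene_id = c("A", "B", "C", "D"),
                      start = c(100, 200, 300, 400),
                      end = c(150, 250, 350, 450),
                      stringsAsFactors = FALSE)
  hit <- function(q, s, id) data.frame(
    query_id = q, subject_id = s, identity_pct = id, ratio_q = 1,
    ratio_s = 1, stringsAsFactors = FALSE)
  # A-B and B-C pass, A-C fails: one transitive group {A,B,C}
  hits <- rbind(hit("A", "B", 80), hit("B", "C", 80), hit("A", "C", 10))
  grp <- tandem_groups(genes, hits, tandem_setting(2))
  expect_length(grp, 1)
  expect_equal(grp[[1]]$members, c("A", "B", "C"))
  expect_equal(grp[[1]]$representative, "A")
  coll <- collapse_tandems(genes, grp)
  expect_equal(coll$retained$gene_id, c("A", "D"))
  expect_equal(coll$removed, c("B", "C"))
  # idempotence
  again <- collapse_tandems(coll$retained, tandem_groups(
    coll$retained, hits, tandem_setting(2)))
  expect_equal(again$retained, coll$retained)
  expect_equal(again$removed, character())
  # nothing passes -> no groups, no removals
  expect_length(tandem_groups(genes, hit("A", "B", 10),
                              tandem_setting(2)), 0)
  coll0 <- collapse_tandems(genes, list())
  expect_equal(coll0$retained, genes)
  expect_equal(coll0$removed, character())
})

test_that("removed-gene count is non-increasing from setting_1 to 4", {
  base <- fixed_protein(250, seed = 20)
  prots <- withr::with_seed(21, c(
    g1 = base,
    g2 = mutate_protein(base, 0.95),
    g3 = mutate_protein(base, 0.6),
    g4 = fixed_protein(250, seed = 22),
    g5 = fixed_protein(250, seed = 23)))
  genes <- data.frame(gene_id = names(prots),
                      start = seq(100, by = 1000, length.out = 5),
                      end = seq(400, by = 1000, length.out = 5),
                      protein = unname(prots), stringsAsFactors = FALSE)
  hits <- align_window(genes)
  removed <- vapply(1:4, function(i) {
    s <- tandem_setting(i)
    length(collapse_tandems(genes, tandem_groups(genes, hits, s))$removed)
  }, 0L)
  expect_true(all(diff(removed) <= 0))
  expect_gte(removed[[1]], 1)  # the 60%-identity copy is caught loosely
})

test_that("mutated pairs align near the expected identity", {
  # redraw-from-20 mutation at per-site rate m: expected identity
  # 100 * (1 - m * 19/20), aligner within 3 points on 300 aa
  for (m in c(0.05, 0.15)) {
    ok <- withr::with_seed(30 + round(100 * m), {
      vapply(1:8, function(i) {
        base <- random_protein(300)
        ch <- strsplit(base, "")[[1]]
        hitpos <- runif(300) < m
        ch[hitpos] <- sample(AA20, sum(hitpos), replace = TRUE)
        h <- align_pair(base, paste(ch, collapse = ""))
        abs(h$identity_pct - 100 * (1 - m * 19 / 20)) <= 3
      }, NA)
    })
    expect_gte(mean(ok), 7 / 8)
  }
})

test_that("seeded window alignment finds what exhaustive alignment finds", {
  # the prescreen must not change tandem calls at its setting
  base <- fixed_protein(300, seed = 40)
  prots <- withr::with_seed(41, c(
    t1 = base, t2 = mutate_protein(base, 0.95),
    t3 = mutate_protein(base, 0.95),
    x1 = random_protein(280), x2 = random_protein(320),
    x3 = random_protein(300)))
  genes <- data.frame(gene_id = names(prots),
                      start = seq(100, by = 1000, length.out = 6),
                      end = seq(500, by = 1000, length.out = 6),
                      protein = unname(prots), stringsAsFactors = FALSE)
  s2 <- tandem_setting(2)
  seeded <- align_window(genes, setting = s2)
  full <- align_window(genes)
  key <- function(h) {
    h <- h[passes_setting(h, s2), ]
    sort(paste(h$query_id, h$subject_id))
  }
  expect_equal(key(seeded), key(full))
  expect_lte(nrow(seeded), nrow(full))
})

test_that("blast-style TSV round-trips hit fields", {
  prots <- c(a = fixed_protein(200, seed = 50),
             b = fixed_protein(200, seed = 50),  # identical pair
             c = fixed_protein(220, seed = 51))
  hits <- align_pairs(prots)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tsv(hits, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(header[1:6],
               c("Query_id", "len_query", "Subject_id", "len_subject",
                 "identity", "alignment_length"))
  expect_length(header, 19)
  back <- read_blast_tsv(path)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$align_len, hits$align_len)
  expect_equal(back$identity_pct, round(hits$identity_pct, 2))
})
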