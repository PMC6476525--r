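test_that("transcript normalization maps RNA to DNA and enforces CDS bounds", {
  tx <- transcript("x", "AAAUGGGCTAAAA", cds_start = 3, cds_end = 11)
  expect_equal(tx$seq, "AAATGGGCTAAAA")
  u <- extract_utrs(tx)
  expect_equal(nchar(u$utr5$seq), 2L)
  expect_equal(nchar(u$utr3$seq), 2L)

  expect_error(transcript("bad", "ACGTACGT", 2, 9), "invalid CDS")
  expect_error(transcript("bad", "ACGTACGT", 5, 3), "invalid CDS")
  expect_error(transcript("bad", "ACXTACGT", 1, 6), "non-nucleotide")
  expect_error(transcript("bad", "ANNNNACG", 1, 6), "are N")
})

test_that("validate_cds enforces frame, start and stop only when asked", {
  seq <- paste0("GG", "ATGAAATAA", "CC")
  expect_silent(transcript("ok", seq, 3, 11, validate_cds = TRUE))
  expect_error(transcript("frame", seq, 3, 10, validate_cds = TRUE),
               "multiple of 3")
  noatg <- paste0("GG", "TTGAAATAA", "CC")
  expect_error(transcript("start", noatg, 3, 11, validate_cds = TRUE),
               "ATG")
  expect_silent(transcript("start", noatg, 3, 11))  # off by default
})

test_that("extract_utrs marks absent UTRs explicitly and partitions the sequence", {
  tx <- transcript("full", "ATGAAATAA", 1, 9)
  u <- extract_utrs(tx)
  expect_null(u$utr5)
  expect_null(u$utr3)

  set.seed(11)
  for (k in 1:25) {
    u5 <- sample(0:30, 1); cl <- 3 * sample(2:20, 1); u3 <- sample(0:60, 1)
    seq <- random_seq(u5 + cl + u3)
    tx <- transcript("p", seq, u5 + 1, u5 + cl)
    u <- extract_utrs(tx)
    len5 <- if (is.null(u$utr5)) 0L else nchar(u$utr5$seq)
    len3 <- if (is.null(u$utr3)) 0L else nchar(u$utr3$seq)
    expect_equal(len5 + cl + len3, nchar(seq))
    if (!is.null(u$utr3))
      expect_identical(u$utr3$seq, substr(seq, u5 + cl + 1, nchar(seq)))
  }
})

test_that("subregion uses 1-based inclusive coordinates and composes", {
  s <- paste(rep("ACGT", 400), collapse = "")
  expect_equal(nchar(subregion(s, 79, 153)$seq), 75L)
  expect_equal(nchar(subregion(s, 1112, 1252)$seq), 141L)
  expect_equal(nchar(subregion(s, 1183, 1252)$seq), 70L)
  expect_equal(nchar(subregion(s, 7, 7)$seq), 1L)
  expect_error(subregion(s, 0, 10), "out of bounds")
  expect_error(subregion(s, 10, 1601), "out of bounds")

  set.seed(5)
  for (k in 1:100) {
    n <- sample(20:200, 1)
    s <- random_seq(n)
    a <- sample(1:(n - 10), 1); b <- sample((a + 5):n, 1)
    inner_len <- b - a + 1
    c_ <- sample(1:(inner_len - 1), 1); d <- sample(c_:inner_len, 1)
    expect_identical(subregion(subregion(s, a, b), c_, d)$seq,
                     subregion(s, a + c_ - 1, a + d - 1)$seq)
  }
})

test_that("revcomp is an involution over ACGTN", {
  expect_equal(revcomp("ATGC"), "GCAT")
  expect_equal(revcomp("NNN"), "NNN")
  expect_error(revcomp("ATXG"), "non-nucleotide")
  set.seed(21)
  for (k in 1:100) {
    s <- random_seq(50)
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("FASTA + CDS table round-trips and reports unmapped records", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fa"); tab <- file.path(dir, "t.tsv")
  txs <- list(
    transcript("tx1", "GGATGAAATAACC", 3, 11, gene = "G1", species = "human"),
    transcript("tx2", "TTTATGCCCTGAAAAA", 4, 12, gene = "G2", species = "pig"))
  names(txs) <- c("tx1", "tx2")
  write_transcripts(txs, fa, tab)
  back <- read_transcripts(fa, tab)
  expect_identical(back$tx1, txs$tx1)
  expect_identical(back$tx2, txs$tx2)

  # drop tx2's coordinate row: strict mode is fatal naming the record,
  # lenient mode still parses tx1 and lists the problem
  t2 <- utils::read.delim(tab)
  utils::write.table(t2[t2$id != "tx2", ], tab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_transcripts(fa, tab), "tx2")
  res <- read_transcripts(fa, tab, strict = FALSE)
  expect_named(res, "tx1")
  expect_identical(attr(res, "problems")$id, "tx2")
})

test_that("read_transcripts rejects out-of-bounds CDS coordinates fatally", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "t.fa"); tab <- file.path(dir, "t.tsv")
  writeLines(c(">short", "ACGTACGT"), fa)
  writeLines(c("id\tgene\tspecies\tcds_start\tcds_end",
               "short\tG\thuman\t2\t9"), tab)
  expect_error(read_transcripts(fa, tab), "short")
})

test_that("GenBank flat records parse single-interval CDS features", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "r.gb")
  writeLines(c(
    "LOCUS       DEMO1        13 bp    mRNA    linear   PRI 01-JAN-2000",
    "DEFINITION  synthetic demo record.",
    "VERSION     DEMO1.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..13",
    '                     /organism="Homo sapiens"',
    "     CDS             3..11",
    '                     /gene="DEMO"',
    "ORIGIN",
    "        1 aaatgggcta aaa",
    "//"), gb)
  recs <- read_genbank(gb)
  expect_named(recs, "DEMO1.1")
  tx <- recs[[1]]
  expect_equal(tx$seq, "AAATGGGCTAAAA")
  expect_equal(c(tx$cds_start, tx$cds_end), c(3L, 11L))
  expect_equal(tx$gene, "DEMO")
  expect_equal(tx$species, "Homo sapiens")

  writeLines(c(
    "LOCUS       DEMO2        13 bp    mRNA    linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..6,8..13)",
    "ORIGIN",
    "        1 aaatgggcta aaa",
    "//"), gb)
  expect_error(read_genbank(gb), "single-interval")
})

test_that("region_report tabulates UTR and CDS coordinates", {
  txs <- list(transcript("t1", "GGATGAAATAACC", 3, 11))
  rep <- region_report(txs)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$length[rep$kind == "cds"], 9L)
  expect_equal(sum(rep$length), 13L)
})
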