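test_that("FASTA reading validates, anchors and round-trips", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACGTACGT", ">p2 descr", "ggttaacc"), fa)
  seqs <- readSequences(fa)
  expect_named(seqs, c("p1", "p2"))
  expect_equal(unname(seqs["p2"]), "GGTTAACC")  # case-folded

  out <- tempfile(fileext = ".fasta")
  writeSequences(seqs, out)
  expect_equal(unname(readSequences(out)), unname(seqs))

  # anchor convention: a 400-nt promoter spans -400..-1
  expect_equal(anchorCoord(1L, 400L), -400L)
  expect_equal(anchorCoord(400L, 400L), -1L)
  expect_equal(unanchorCoord(-400L, 400L), 1L)
  expect_equal(unanchorCoord(anchorCoord(137L, 400L), 400L), 137L)
})

test_that("FASTA errors name the offending record", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACNT"), fa)
  expect_error(readSequences(fa), "bad")
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACGT", ">dup", "AAGT"), fa2)
  expect_error(readSequences(fa2), "duplicate")
})

test_that("MEME minimal motif format reads, validates and round-trips", {
  path <- system.file("extdata", "regulon_catalog_synthetic_37.meme",
                      package = "PromoterForge")
  cat37 <- readMotifs(path)
  expect_length(cat37, 37L)
  for (m in cat37[1:3])
    expect_true(all(abs(colSums(freqMatrix(m)) - 1) < 1e-6))

  out <- tempfile(fileext = ".meme")
  writeMotifs(cat37, out)
  back <- readMotifs(out)
  expect_equal(vapply(back, motifName, character(1)),
               vapply(cat37, motifName, character(1)))
  expect_equal(freqMatrix(back[[5]]), freqMatrix(cat37[[5]]),
               tolerance = 1e-5)
})

test_that("motif parser handles degenerate and malformed matrices", {
  f <- tempfile()
  writeLines(c("MEME version 4", "", "MOTIF one",
               "letter-probability matrix: alength= 4 w= 1",
               "1.0 0.0 0.0 0.0"), f)
  m <- readMotifs(f)[[1]]
  expect_equal(motifLength(m), 1L)
  expect_equal(unname(freqMatrix(m)[, 1]), c(1, 0, 0, 0))

  f2 <- tempfile()
  writeLines(c("MOTIF twice",
               "letter-probability matrix: alength= 4 w= 1",
               "0.5 0.5 0.5 0.5"), f2)
  expect_warning(m2 <- readMotifs(f2), "renormalized")
  expect_equal(sum(freqMatrix(m2[[1]])), 1)

  f3 <- tempfile()
  writeLines(c("MOTIF bad",
               "letter-probability matrix: alength= 4 w= 1",
               "0.5 0.5 0.5"), f3)
  expect_error(readMotifs(f3), "3 fields")

  f4 <- tempfile()
  writeLines(c("MOTIF neg",
               "letter-probability matrix: alength= 4 w= 1",
               "1.2 -0.2 0.0 0.0"), f4)
  expect_error(readMotifs(f4), "negative")
})

test_that("config loading applies defaults, overrides and validation", {
  empty <- tempfile(fileext = ".yaml")
  file.create(empty)
  cfg <- suppressMessages(loadConfig(empty))
  expect_equal(cfg@paddingValue, 0.25)
  expect_equal(cfg@nPermutations, 100L)
  expect_equal(cfg@prevalenceThreshold, 6.5)
  expect_equal(cfg@windowRadius, 4L)
  expect_equal(cfg@crossDatasetRadius, 20L)
  expect_equal(cfg@spearmanCutoff, 0.99)
  expect_equal(cfg@cvRepeats, 10L)

  ov <- tempfile(fileext = ".yaml")
  writeLines("alpha: 0.01", ov)
  expect_equal(suppressMessages(loadConfig(ov))@alpha, 0.01)

  bad <- tempfile(fileext = ".yaml")
  writeLines("groupFraction: 1.5", bad)
  expect_error(suppressMessages(loadConfig(bad)), "0, 1")

  unk <- tempfile(fileext = ".yaml")
  writeLines("alhpa: 0.01", unk)
  expect_error(suppressMessages(loadConfig(unk)), "unknown")
})

test_that("TSV tables round-trip and validate", {
  df <- data.frame(gene_id = c("g1", "g2"), expr_dnt = c(5.5, 2.0),
                   expr_ctrl = c(1.5, 2.5))
  p <- tempfile(fileext = ".tsv")
  writeExpressionTable(df, p)
  back <- readExpressionTable(p)
  expect_equal(back$delta, c(4.0, -0.5))

  em <- readEnergyMatrix(system.file("extdata", "energy_matrix_synthetic.tsv",
                                     package = "PromoterForge"))
  expect_equal(dim(em), c(4L, 41L))
  expect_identical(rownames(em), c("A", "C", "G", "T"))
})
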