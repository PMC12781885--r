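mkPlan <- function(m, position, direction = "maximize") {
  structure(list(motif = m, direction = direction,
                 target_position = as.integer(position),
                 score_target = 0, score_reference = 1, decision = TRUE),
            class = "InsertionPlan")
}

test_that("the constraint mask covers the restriction sites", {
  ctrl <- paste0(randSeq(30, seed = 2), "GGTACC", randSeq(30), "ATTTAAAT",
                 randSeq(26))
  mask <- constraintMask(ctrl)
  expect_length(mask, 14L)
  len <- nchar(ctrl)
  expect_true(all(anchorCoord(31:36, len) %in% mask))   # KpnI span
  expect_true(all(anchorCoord(67:74, len) %in% mask))   # SwaI span
})

test_that("refinement reaches the exhaustive optimum with a monotone trace", {
  set.seed(71)
  prom <- randSeq(80)
  for (i in 1:10) {
    L <- sample(3:6, 1)
    m <- randomPSSM(L)
    rng <- bruteForceScoreRange(m)
    pos <- anchorCoord(20L, 80L)

    up <- refineMotifSequence(prom, mkPlan(m, pos, "maximize"))
    expect_equal(up$score, unname(rng["max"]))
    expect_equal(up$fragment, motifConsensus(m))
    if (nrow(up$trace) > 1) expect_true(all(diff(up$trace$score) > 0))
    expect_lte(nrow(up$trace), 3L * L)

    down <- refineMotifSequence(prom, mkPlan(m, pos, "minimize"))
    expect_equal(down$score, unname(rng["min"]))
    if (nrow(down$trace) > 1) expect_true(all(diff(down$trace$score) < 0))
  }
})

test_that("a site already at the optimum takes zero iterations", {
  m <- sharpPSSM("GTACGT")
  prom <- withSite(randSeq(50, seed = 5), "GTACGT", 11L)
  r <- refineMotifSequence(prom, mkPlan(m, anchorCoord(11L, 50L)))
  expect_equal(nrow(r$trace), 0L)
  expect_equal(r$fragment, r$initial)
})

test_that("masked positions are respected and a fully-masked site errors", {
  m <- sharpPSSM("AAAAAA")
  prom <- paste(rep("C", 40), collapse = "")
  pos <- anchorCoord(10L, 40L)
  coords <- anchorCoord(10:15, 40L)
  r <- refineMotifSequence(prom, mkPlan(m, pos), mask = coords[1:2])
  expect_equal(substr(r$fragment, 1, 2), "CC")  # masked bases untouched
  expect_equal(substr(r$fragment, 3, 6), "AAAA")
  expect_error(refineMotifSequence(prom, mkPlan(m, pos), mask = coords),
               "no mutable")
})

test_that("library combinatorics: singles plus non-overlapping pairs", {
  ctrl <- paste0(randSeq(40, seed = 31), "GGTACC", randSeq(100),
                 "ATTTAAAT", randSeq(54))
  len <- nchar(ctrl)
  mkSharp <- function(seed) {
    set.seed(seed)
    sharpPSSM(randSeq(6))
  }
  # A plans at indices 50, 60, 70; B plans at 90, 100, 110, 120 (disjoint)
  plansA <- lapply(c(50L, 60L, 70L), function(i)
    mkPlan(mkSharp(i), anchorCoord(i, len)))
  plansB <- lapply(c(90L, 100L, 110L, 120L), function(i)
    mkPlan(mkSharp(i), anchorCoord(i, len)))
  lib <- buildVariantLibrary(ctrl, plansA, plansB)
  expect_equal(length(lib$variants), 3L + 4L + 12L)
  expect_equal(nrow(lib$rejected), 0L)

  # overlap by one base removes exactly that pair
  plansB2 <- plansB
  plansB2[[1L]] <- mkPlan(mkSharp(90L), anchorCoord(54L, len))  # hits A@50-55
  lib2 <- buildVariantLibrary(ctrl, plansA, plansB2)
  expect_equal(length(lib2$variants), 18L)

  # a plan editing inside the KpnI span is rejected by name
  plansA3 <- c(plansA, list(mkPlan(mkSharp(7L), anchorCoord(43L, len))))
  lib3 <- buildVariantLibrary(ctrl, plansA3, plansB)
  expect_equal(nrow(lib3$rejected), 1L)
  expect_match(lib3$rejected$reason, "masked coordinate")
  expect_equal(length(lib3$variants), 19L)
})

test_that("every variant differs from control and keeps restriction sites", {
  ctrl <- paste0(randSeq(40, seed = 91), "GGTACC", randSeq(100),
                 "ATTTAAAT", randSeq(54))
  len <- nchar(ctrl)
  set.seed(13)
  plansA <- lapply(c(20L, 120L), function(i)
    mkPlan(randomPSSM(7), anchorCoord(i, len)))
  plansB <- lapply(c(60L, 160L), function(i)
    mkPlan(randomPSSM(5), anchorCoord(i, len)))
  lib <- buildVariantLibrary(ctrl, plansA, plansB)
  for (v in lib$variants) {
    expect_true(v$sequence != ctrl)
    expect_gte(nrow(v$edits), 1L)
    expect_length(intersect(v$edits$coordinate, constraintMask(ctrl)), 0L)
    expect_true(grepl("GGTACC", v$sequence, fixed = TRUE))
    expect_true(grepl("ATTTAAAT", v$sequence, fixed = TRUE))
    # applying the edit manifest to the control reproduces the sequence
    mf <- mutationFeatures(v$sequence, ctrl)
    expect_equal(mf$count, nrow(v$edits))
    expect_setequal(as.integer(names(mf$vector))[mf$vector == 1],
                    v$edits$coordinate)
  }
})
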