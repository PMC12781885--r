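test_that("folding profiles have one window per start and sane energies", {
  seq100 <- randSeq(100, seed = 301)
  fp <- foldingProfile(seq100)
  expect_equal(nrow(fp$windows), 61L)          # 100 - 40 + 1
  expect_equal(fp$windows$position[1], -100L)
  expect_equal(fp$average, mean(fp$windows$mfe))

  polyA <- paste(rep("A", 40), collapse = "")
  expect_equal(rnaFoldMFE(polyA), 0)

  short <- foldingProfile(randSeq(30, seed = 302))
  expect_equal(nrow(short$windows), 0L)
  expect_true(is.finite(short$total))
})

test_that("a perfect stem folds to the energy of its known structure", {
  # 12-bp GC stem closed by a tetraloop: the MFE structure is the full stem,
  # so evaluating that structure with the same thermodynamic parameters
  # (RNAeval) must reproduce the MFE
  stem <- "GGGGGGGGGGGGAAAACCCCCCCCCCCC"
  mfe <- rnaFoldMFE(stem)
  expect_lt(mfe, 0)
  ev <- system2(Sys.which("RNAeval"), character(0),
                input = c(stem, "((((((((((((....))))))))))))"), stdout = TRUE)
  evE <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                        grep("\\)\\s*$", ev, value = TRUE)))
  expect_equal(mfe, evE, tolerance = 0.1)
})

test_that("mutation features mirror the edit set", {
  ctrl <- randSeq(60, seed = 311)
  self <- mutationFeatures(ctrl, ctrl)
  expect_equal(self$count, 0)
  expect_true(all(self$vector == 0))

  v <- strsplit(ctrl, "")[[1]]
  at <- c(5L, 20L, 44L)
  for (i in at) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  mf <- mutationFeatures(paste(v, collapse = ""), ctrl)
  expect_equal(mf$count, 3)
  expect_setequal(as.integer(names(mf$vector))[mf$vector == 1],
                  anchorCoord(at, 60L))
  expect_error(mutationFeatures("ACGT", ctrl), "lengths differ")
})

test_that("ChimeraARS matches its closed forms and a brute-force oracle", {
  ref <- randSeq(40, seed = 321)
  expect_equal(chimeraARS(ref, ref), (40 + 1) / 2)
  expect_equal(chimeraARS("TTT", c("ACGAC", "GGCCA")), 0)

  brute <- function(s, refs) {
    n <- nchar(s)
    mean(vapply(seq_len(n), function(p) {
      l <- 0L
      while (p + l <= n) {
        sub <- substr(s, p, p + l)
        if (!any(vapply(refs, function(r) grepl(sub, r, fixed = TRUE),
                        logical(1)))) break
        l <- l + 1L
      }
      as.numeric(l)
    }, numeric(1)))
  }
  set.seed(323)
  for (i in 1:50) {
    s <- randSeq(sample(10:50, 1))
    refs <- vapply(1:3, function(j) randSeq(sample(10:50, 1)), character(1))
    expect_equal(chimeraARS(s, refs), brute(s, refs))
  }
})

test_that("motif score features are the sliding maxima", {
  seqs <- setNames(c(randSeq(50, seed = 331), randSeq(50)), c("a", "b"))
  u <- uniformPSSM(6)
  expect_equal(unname(motifScoreFeatures(seqs[["a"]], list(u))), 0)
  m <- sharpPSSM("ACGTTG")
  planted <- withSite(seqs[["a"]], "ACGTTG", 20L)
  expect_equal(unname(motifScoreFeatures(planted, list(m))),
               scoreWindow(m, "ACGTTG"))
  expect_warning(motifScoreFeatures("ACG", list(m)), "omitted")
})

test_that("promoter strength sums matrix contributions additively", {
  len <- 60L
  seqv <- randSeq(len, seed = 341)
  zero <- matrix(0, 4, 41, dimnames = list(c("A", "C", "G", "T"), -41:-1))
  st0 <- promoterStrength(seqv, zero, tss = -1L)
  expect_equal(st0$total, 0)

  toy <- zero
  toy["A", ] <- 1        # counts A's in the window
  toy["G", "-10"] <- 5
  st <- promoterStrength(seqv, toy, tss = -1L)
  win <- substr(seqv, unanchorCoord(-42L, len), unanchorCoord(-2L, len))
  nA <- sum(strsplit(win, "")[[1]] == "A")
  baseAtM10 <- substr(seqv, unanchorCoord(-11L, len), unanchorCoord(-11L, len))
  expect_equal(st$total, nA + if (baseAtM10 == "G") 5 else 0)

  # substituting one base changes the total by that column's delta only
  v <- strsplit(seqv, "")[[1]]
  idx <- unanchorCoord(-11L, len)
  old <- v[idx]; v[idx] <- setdiff(c("A", "C", "G", "T"), old)[1]
  st2 <- promoterStrength(paste(v, collapse = ""), toy, tss = -1L)
  expect_equal(st2$total - st$total,
               toy[v[idx], "-10"] - toy[old, "-10"])
  expect_error(promoterStrength("ACGT", toy, tss = -1L), "outside")
})

test_that("composition counts and anti-SD hybridization behave", {
  cmp <- compositionAndRbs("ACGT")$composition
  expect_equal(unname(cmp[paste0("count_", c("A", "C", "G", "T"))]),
               rep(1, 4))
  expect_equal(unname(cmp["GC"]), 0.5)

  s <- randSeq(40, seed = 351)
  cmp2 <- compositionAndRbs(s)$composition
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  expect_equal(sum(cmp2[paste0("count_", dinucs)]), 39)

  # a window reverse-complementary to the anti-SD core pairs most strongly
  sdWin <- "AGGAGG"  # Shine-Dalgarno consensus
  host <- withSite(randSeq(40, seed = 353), sdWin, 15L)
  rbs <- compositionAndRbs(host)$rbs
  expect_equal(nrow(rbs), 35L)
  best <- rbs$position[which.min(rbs$energy)]
  expect_true(abs(best - anchorCoord(15L, 40L)) <= 1)
  expect_lt(min(rbs$energy), 0)
})

test_that("feature reduction removes only genuinely redundant features", {
  set.seed(361)
  n <- 12L
  base <- rnorm(n)
  vals <- cbind(fold_1 = base, fold_2 = base + 1e-9 * rnorm(n),
                fold_3 = rnorm(n), mut_m10 = rbinom(n, 1, 0.5))
  colnames(vals) <- c("fold_-100", "fold_-99", "fold_-50", "mut_-10")
  rownames(vals) <- paste0("v", 1:n)
  ft <- featureTable(vals, c("folding", "folding", "folding", "mutation"))
  red <- reduceFeatures(ft)
  expect_equal(red$dropped, "fold_-99")      # rho ~ 1 duplicate
  expect_true("fold_-50" %in% featureMeta(red$table)$feature)

  # uncorrelated pair both survive; post-condition: no remaining pair
  # above the cutoff
  kept <- featureValues(red$table)
  fkept <- kept[, grepl("^fold_", colnames(kept)), drop = FALSE]
  if (ncol(fkept) >= 2) {
    rho <- abs(cor(fkept, method = "spearman"))
    diag(rho) <- 0
    expect_true(all(rho <= 0.99))
  }

  # adjacent mutation coordinates merge into one averaged profile
  vals2 <- cbind(`mut_-20` = rbinom(n, 1, .5), `mut_-19` = rbinom(n, 1, .5),
                 `mut_-5` = rbinom(n, 1, .5))
  rownames(vals2) <- paste0("v", 1:n)
  ft2 <- featureTable(vals2, "mutation")
  red2 <- reduceFeatures(ft2)
  expect_true("mut_-20_-19" %in% featureMeta(red2$table)$feature)
  expect_true("mut_-5" %in% featureMeta(red2$table)$feature)
  expect_equal(featureValues(red2$table)[, "mut_-20_-19"],
               rowMeans(vals2[, 1:2]))

  # constant features are kept and flagged
  vals3 <- cbind(`fold_-80` = rep(1, n), `fold_-70` = rnorm(n))
  rownames(vals3) <- paste0("v", 1:n)
  red3 <- reduceFeatures(featureTable(vals3, "folding"))
  expect_equal(red3$constant, "fold_-80")
  expect_equal(ncol(featureValues(red3$table)), 2L)
})

test_that("extraction is a pure function of its inputs", {
  ctrl <- randSeq(70, seed = 371)
  set.seed(372)
  vars <- vapply(1:4, function(i) {
    v <- strsplit(ctrl, "")[[1]]
    j <- sample(70, 2)
    for (k in j) v[k] <- setdiff(c("A", "C", "G", "T"), v[k])[1]
    paste(v, collapse = "")
  }, character(1))
  names(vars) <- paste0("v", 1:4)
  ft1 <- extractFeatures(vars, ctrl, includeFolding = FALSE)
  ft2 <- extractFeatures(vars, ctrl, includeFolding = FALSE)
  expect_identical(featureValues(ft1), featureValues(ft2))
  expect_false(anyNA(featureValues(ft1)))
  expect_false(anyDuplicated(featureMeta(ft1)$feature) > 0)
})
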