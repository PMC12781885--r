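test_that("a planted consensus site is found at its coordinate", {
  planted <- "TTGACGGCTA"
  m <- sharpPSSM(planted)
  found <- vapply(1:10, function(s) {
    set.seed(600 + s)
    prom <- withSite(randSeq(400), planted, unanchorCoord(-120L, 400L))
    hits <- significantPositions(m, prom, nPerm = 100, seed = 600 + s)$hits
    -120L %in% hits$position
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("a uniform motif yields no significant positions", {
  set.seed(9)
  u <- uniformPSSM(6)
  res <- significantPositions(u, randSeq(200), nPerm = 50, seed = 10)
  expect_equal(nrow(res$hits), 0L)
  expect_true(all(res$profile$p == 1))  # all scores tie at 0
})

test_that("window aggregation reproduces the worked prevalence example", {
  hits <- data.frame(
    motif = "m",
    promoter_id = c(paste0("p", 1:3), paste0("q", 1:2), "r1"),
    position = c(-10L, -10L, -10L, -12L, -12L, -40L))
  w <- aggregateWindows(hits, radius = 4L)
  best <- w$best
  expect_equal(best$center, -10L)
  expect_equal(best$start, -14L)
  expect_equal(best$end, -6L)
  expect_equal(best$X, 5L)
  expect_equal(best$percent, 500 / 6, tolerance = 1e-9)

  single <- aggregateWindows(data.frame(motif = "m", promoter_id = "p",
                                        position = -33L))
  expect_equal(single$best$percent, 100)

  # symmetric ties break toward the smaller |center|
  tied <- data.frame(motif = "m", promoter_id = c("a", "b"),
                     position = c(-30L, -10L))
  expect_equal(aggregateWindows(tied)$best$center, -10L)
})

test_that("harmonization applies the strict prevalence and radius rules", {
  bestA <- data.frame(motif = "ma", center = -100L, start = -104L,
                      end = -96L, X = 5L, percent = 50)
  mkB <- function(center, percent)
    data.frame(motif = "mb", center = center, start = center - 4L,
               end = center + 4L, X = 10L, percent = percent)
  matches <- data.frame(motif_a = "ma", motif_b = "mb", index_b = 1L,
                        similarity = 0.9, offset = 0L, p = 0.01,
                        significant = TRUE)

  # exact 6.5% is excluded (strict ">")
  h <- filterAndHarmonize(bestA, mkB(-100L, 6.5), matches)
  expect_equal(nrow(h), 0L)
  h2 <- filterAndHarmonize(bestA, mkB(-100L, 6.6), matches)
  expect_true("datasetB" %in% h2$source)

  # within the +/-20 nt radius: kept, midpoint rounded toward A
  h3 <- filterAndHarmonize(bestA, mkB(-115L, 30), matches)
  a3 <- h3[h3$source == "datasetA", ]
  expect_equal(nrow(a3), 1L)
  expect_equal(a3$position, -107L)

  # outside the radius: A motif dropped, B motif retained
  h4 <- filterAndHarmonize(bestA, mkB(-130L, 30), matches)
  expect_equal(sum(h4$source == "datasetA"), 0L)
  expect_equal(sum(h4$source == "datasetB"), 1L)
})

test_that("insertion decisions follow the strict score comparison", {
  m <- sharpPSSM("ACGTAC")
  len <- 200L
  prom <- withSite(randSeq(len, seed = 4), "ACGTAC", 100L)
  pos <- anchorCoord(100L, len)

  mkHits <- function(score) data.frame(position = c(-50L, -60L),
                                       score = c(score, score - 1))
  realScore <- scoreWindow(m, "ACGTAC")

  over <- decideInsertion(m, prom, targetPositions = pos,
                          sourceHits = mkHits(realScore + 2),
                          direction = "maximize")
  expect_true(over$decision)  # target weaker than reference -> insert
  expect_equal(over$target_position, pos)

  eq <- decideInsertion(m, prom, targetPositions = pos,
                        sourceHits = data.frame(position = -50L,
                                                score = realScore),
                        direction = "maximize")
  expect_false(eq$decision)  # strict inequality
  eqMin <- decideInsertion(m, prom, targetPositions = pos,
                           sourceHits = data.frame(position = -50L,
                                                   score = realScore),
                           direction = "minimize")
  expect_false(eqMin$decision)

  under <- decideInsertion(m, prom, targetPositions = pos,
                           sourceHits = mkHits(realScore - 3),
                           direction = "minimize")
  expect_true(under$decision)  # target stronger than reference -> remove

  expect_error(decideInsertion(m, prom, targetPositions = integer(0),
                               sourceHits = mkHits(1), "maximize"),
               "candidate")
})

test_that("reference score is the max of per-position means", {
  m <- sharpPSSM("AAAAAA")
  prom <- randSeq(100, seed = 12)
  hits <- data.frame(position = c(-50L, -50L, -70L),
                     score = c(4, 6, 5.5))
  pl <- decideInsertion(m, prom, targetPositions = -30L,
                        sourceHits = hits, direction = "maximize")
  expect_equal(pl$score_reference, 5.5)  # mean(4,6)=5 < 5.5
})

test_that("planted sites across promoters select a window containing them", {
  planted <- "TTGACGGCTA"
  m <- sharpPSSM(planted)
  set.seed(888)
  proms <- vapply(1:12, function(i) {
    s <- randSeq(300)
    if (i <= 5) withSite(s, planted, unanchorCoord(-120L, 300L)) else s
  }, character(1))
  names(proms) <- paste0("p", 1:12)
  hits <- collectHits(m, proms, nPerm = 100, seed = 999)
  best <- aggregateWindows(hits)$best
  expect_true(best$start <= -120 && -120 <= best$end)
})
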