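test_that("time standardization interpolates and holds boundaries", {
  mk <- function(t, dnt, ctrl, id = "v1")
    data.frame(variant_id = id, replicate = 1L, time = t,
               lum_dnt = dnt, lum_ctrl = ctrl)
  s <- mk(0:3, c(10, 11, 13, 12), rep(10, 4))
  onGrid <- standardizeTimegrid(s, grid = 0:3)
  expect_equal(unname(onGrid[1, ]), c(0, 1, 3, 2))

  s2 <- mk(c(0, 2), c(10, 20), c(10, 10))
  m2 <- standardizeTimegrid(s2, grid = c(0, 1, 2))
  expect_equal(unname(m2[1, 2]), 5)           # linear midpoint
  m3 <- standardizeTimegrid(s2, grid = c(-1, 0, 3))
  expect_equal(unname(m3[1, 1]), 0)           # boundary held
  expect_equal(unname(m3[1, 3]), 10)

  expect_error(standardizeTimegrid(mk(1, 5, 3), grid = 0:2), "single")
})

test_that("response variables match the hand-worked example", {
  rv <- responseVariables(c(0, 1, 3, 2), 0:3)
  expect_equal(rv$max_diff, 3)
  expect_equal(rv$avg_diff, 1.5)
  expect_equal(rv$max_slope, 2)
  expect_equal(rv$time_to_max, 2)

  cst <- responseVariables(rep(4, 5), 0:4)
  expect_equal(cst$max_diff, 4)
  expect_equal(cst$avg_diff, 4)
  expect_equal(cst$max_slope, 0)
  expect_equal(cst$time_to_max, 0)

  sc <- responseVariables(10 * c(0, 1, 3, 2), 0:3)
  expect_equal(sc$max_diff, 30)
  expect_equal(sc$max_slope, 20)
  expect_equal(sc$time_to_max, 2)
})

test_that("correlation clustering recovers shape groups invariantly", {
  set.seed(401)
  t <- seq(0, 3, length.out = 12)
  g1 <- t(vapply(1:15, function(i) runif(1, 1, 6) * sin(t),
                 numeric(12)))
  g2 <- t(vapply(1:15, function(i) runif(1, 1, 6) * t^2, numeric(12)))
  mat <- rbind(g1, g2)
  rownames(mat) <- paste0("v", 1:30)
  colnames(mat) <- t
  cr <- clusterResponses(mat, Ks = 2:4, seed = 5)
  expect_equal(cr$K, 2L)
  expect_length(unique(cr$labels[1:15]), 1L)
  expect_length(unique(cr$labels[16:30]), 1L)

  # per-profile affine rescaling leaves the labels unchanged
  mat2 <- mat * runif(30, 0.5, 2)
  cr2 <- clusterResponses(mat2, Ks = 2:4, seed = 5)
  agree <- mean((cr$labels[1:15][1] == cr$labels) ==
                (cr2$labels[1:15][1] == cr2$labels))
  expect_equal(agree, 1)

  cr3 <- clusterResponses(mat, Ks = 2:4, seed = 5)
  expect_identical(cr$labels, cr3$labels)
})

test_that("a planted linear response is recovered across model families", {
  set.seed(402)
  n <- 100L; p <- 20L
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("v", 1:n), paste0("f", 1:p)))
  signal <- 3 * X[, 1] - 2 * X[, 2]
  y <- signal + rnorm(n, sd = sd(signal) / sqrt(10))
  rep <- fitRegressors(X, y, cvRepeats = 5L, seed = 7, xgbTrials = 5L)
  expect_gte(median(rep$linear$repeats$validation_r), 0.9)
  expect_gte(median(rep$lasso$repeats$validation_r), 0.9)
  selLin <- table(unlist(rep$linear$selected))
  expect_true(all(c("f1", "f2") %in% names(selLin)[selLin >= 4]))
  # pure noise gives near-zero validation correlation
  y0 <- rnorm(n)
  rep0 <- fitRegressors(X, y0, cvRepeats = 5L, seed = 8, xgbTrials = 3L)
  expect_lte(median(abs(rep0$linear$repeats$validation_r)), 0.45)
  # harness is seed-deterministic
  repA <- fitRegressors(X, y, cvRepeats = 2L, seed = 33, xgbTrials = 2L)
  repB <- fitRegressors(X, y, cvRepeats = 2L, seed = 33, xgbTrials = 2L)
  expect_identical(repA$linear$repeats, repB$linear$repeats)
  expect_identical(repA$xgboost$repeats, repB$xgboost$repeats)
})

test_that("tertile labels are balanced and degenerate ties error", {
  set.seed(403)
  lab <- classLabels(rnorm(31), controlValue = 0)
  expect_lte(diff(range(table(lab$labels))), 1)
  expect_error(classLabels(rep(1, 30), 0), "degenerate")
})

test_that("importance rankings merge windows and satisfy additivity", {
  set.seed(404)
  n <- 60L
  X <- cbind(matrix(rnorm(n * 4), n, 4), rnorm(n), rnorm(n))
  colnames(X) <- c("fold_-200", "fold_-195", "fold_-100", "pssm_ACGTA",
                   "pssm_ACGTT", "strength_total")
  rownames(X) <- paste0("v", 1:n)
  y <- X[, 1] + rnorm(n, sd = 0.3)
  rep <- fitRegressors(X, y, cvRepeats = 4L, seed = 3, xgbTrials = 3L)
  imp <- featureImportance(rep, X, y)
  # windows within 10 nt merged; one-substitution motifs merged
  expect_true("fold_-200_-195" %in% imp$frequency$feature)
  expect_false("fold_-195" %in% imp$frequency$feature)
  expect_false(all(c("pssm_ACGTA", "pssm_ACGTT") %in% imp$frequency$feature))
  # additive attributions (plus baseline) sum to the model prediction
  contrib <- imp$attributionMatrix
  expect_equal(ncol(contrib), ncol(X) + 1L)
  expect_lte(max(abs(rowSums(contrib) - imp$predictions)), 1e-5)
})

test_that("variant significance and the randomization FDR behave", {
  set.seed(405)
  ids <- c("control", paste0("v", 1:40))
  vals <- data.frame(variant_id = rep(ids, each = 3),
                     value = rnorm(123, 10, 1))
  up <- vals$variant_id %in% paste0("v", 1:8)
  vals$value[up] <- vals$value[up] + 10   # strong shift, ~10 sigma
  vs <- variantSignificance(vals, nRandom = 50, seed = 6)
  shifted <- vs$perVariant[vs$perVariant$variant_id %in% paste0("v", 1:8), ]
  expect_true(all(shifted$p < 0.05))
  expect_lt(median(shifted$p), 0.005)
  expect_gte(vs$nSignificant, 8)
  expect_equal(vs$fdr, mean(vs$nullCounts) / vs$nSignificant)
  expect_lte(vs$fdr, 0.5)

  # null data: significant fraction near alpha
  vals0 <- data.frame(variant_id = rep(ids, each = 3),
                      value = rnorm(123, 10, 1))
  vs0 <- variantSignificance(vals0, nRandom = 20, seed = 7)
  expect_lte(vs0$nSignificant / 40, 0.2)
})

test_that("EC200 reproduces the interpolation arithmetic", {
  expect_equal(computeEC200(c(0.2, 0.5, 1), c(1.2, 2, 3.5))$ec200, 0.5)

  # log(ratio)-linear-in-log(dose) interpolation between 0.1 and 1.0:
  # 10^(-1 + (log 2 - log 1.5) / (log 3 - log 1.5)) = 0.26004
  e <- computeEC200(c(0.1, 1.0), c(1.5, 3.0))
  expect_equal(e$ec200,
               10^(-1 + (log(2) - log(1.5)) / (log(3) - log(1.5))),
               tolerance = 1e-12)
  expect_equal(e$ec200, 0.26004, tolerance = 1e-4)

  flat <- computeEC200(c(0.1, 1, 10), c(1.1, 1.5, 1.9))
  expect_false(flat$reached)
  expect_true(is.na(flat$ec200))

  expect_warning(w <- computeEC200(c(0.1, 1, 10, 100), c(1, 3, 1.5, 4)),
                 "non-monotone")
  expect_lt(w$ec200, 1)
})
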