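# Luminescence standardization, response variables, K-selection clustering,
# regression and classification harnesses with forward feature selection,
# importance analysis, variant significance/FDR, and EC200 estimation.

#' @importFrom stats approx cor kmeans quantile rnorm runif sd t.test
#'   wilcox.test predict coef setNames aggregate rgamma
NULL

#' Standardize luminescence series onto a common time grid
#'
#' The net signal delta(t) = lum_dnt - lum_ctrl of each
#' (variant, replicate) series is linearly interpolated onto \code{grid};
#' beyond the measured span the boundary value is held constant.
#'
#' @param series luminescence data.frame (columns \code{variant_id},
#'   \code{replicate}, \code{time}, \code{lum_dnt}, \code{lum_ctrl}).
#' @param grid numeric vector of target time points (hours).
#' @return numeric matrix, one row per variant/replicate (rownames
#'   \code{"<variant>|<replicate>"}), columns = grid; attribute
#'   \code{"grid"}.
#' @export
standardizeTimegrid <- function(series, grid) {
  key <- paste(series$variant_id, series$replicate, sep = "|")
  groups <- split(seq_len(nrow(series)), key)
  rows <- lapply(groups, function(ii) {
    s <- series[ii, ]
    .stopIfNot(nrow(s) >= 2L,
               "series '%s' has a single time point; cannot interpolate",
               key[ii[1L]])
    o <- order(s$time)
    approx(s$time[o], (s$lum_dnt - s$lum_ctrl)[o], xout = grid,
           rule = 2)$y
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(groups)
  colnames(m) <- grid
  attr(m, "grid") <- grid
  m
}

#' Response variables of a net-luminescence curve
#'
#' @param delta net luminescence values.
#' @param t matching time points (hours, strictly increasing).
#' @return list: \code{max_diff}, \code{avg_diff}, \code{max_slope}
#'   (max over consecutive pairs of d(delta)/dt), \code{time_to_max}
#'   (time of the first maximum).
#' @export
responseVariables <- function(delta, t) {
  .stopIfNot(length(delta) == length(t), "delta and t lengths differ")
  slopes <- if (length(delta) >= 2L) diff(delta) / diff(t) else 0
  list(max_diff = max(delta),
       avg_diff = mean(delta),
       max_slope = max(slopes),
       time_to_max = t[which.max(delta)])
}

#' Response variables for a standardized delta matrix
#'
#' @param mat matrix from [standardizeTimegrid()] (or any profiles-by-time
#'   matrix with a \code{"grid"} attribute or numeric colnames).
#' @return data.frame with one row per profile.
#' @export
responseVariableTable <- function(mat) {
  t <- attr(mat, "grid")
  if (is.null(t)) t <- as.numeric(colnames(mat))
  out <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    as.data.frame(responseVariables(mat[i, ], t))
  }))
  out$id <- rownames(mat)
  out[c("id", "max_diff", "avg_diff", "max_slope", "time_to_max")]
}

# Davies-Bouldin index on a feature matrix with Euclidean centroids
.daviesBouldin <- function(x, labels) {
  ks <- sort(unique(labels))
  cents <- t(vapply(ks, function(k)
    colMeans(x[labels == k, , drop = FALSE]), numeric(ncol(x))))
  scat <- vapply(seq_along(ks), function(i) {
    pts <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cents[i, ])^2)))
  }, numeric(1))
  db <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      d <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      (scat[i] + scat[j]) / d
    }, numeric(1)))
  }, numeric(1))
  mean(db)
}

#' Cluster response profiles with a correlation metric
#'
#' Profiles are z-scored row-wise (which makes Euclidean k-means
#' equivalent to clustering by Pearson correlation, and leaves the result
#' invariant to per-profile affine rescaling) and clustered for each
#' candidate K. K is chosen to maximize the silhouette score computed on
#' the 1 - correlation distance; if the Davies-Bouldin index (lower
#' better) prefers a different K, the silhouette choice wins and the
#' disagreement is reported. Constant profiles (undefined correlation)
#' are kept as all-zero rows (Euclidean fallback) and flagged.
#'
#' @param mat profiles-by-time matrix.
#' @param Ks candidate cluster counts (default 2:6).
#' @param seed RNG seed for k-means restarts.
#' @return list: \code{labels}, \code{K}, \code{metrics} (per-K data.frame
#'   silhouette/davies_bouldin), \code{flagged} (constant profile ids),
#'   \code{disagreement}.
#' @export
clusterResponses <- function(mat, Ks = 2:6, seed = 1L) {
  .stopIfNot(nrow(mat) >= 2L * max(Ks), "need at least 2*max(K) profiles")
  sds <- apply(mat, 1L, sd)
  flagged <- rownames(mat)[sds == 0]
  z <- mat
  z[sds > 0, ] <- t(scale(t(mat[sds > 0, , drop = FALSE])))
  z[sds == 0, ] <- 0
  cmat <- suppressWarnings(cor(t(mat)))
  cmat[!is.finite(cmat)] <- 0
  d <- stats::as.dist(1 - cmat)
  .withSeed(seed, {
    fits <- lapply(Ks, function(k) kmeans(z, centers = k, nstart = 10L))
    metrics <- data.frame(
      K = Ks,
      silhouette = vapply(seq_along(Ks), function(i) {
        mean(cluster::silhouette(fits[[i]]$cluster, d)[, "sil_width"])
      }, numeric(1)),
      davies_bouldin = vapply(seq_along(Ks), function(i) {
        .daviesBouldin(z, fits[[i]]$cluster)
      }, numeric(1)))
    iSil <- which.max(metrics$silhouette)
    iDb <- which.min(metrics$davies_bouldin)
    if (iSil != iDb)
      message("silhouette (K=", Ks[iSil], ") and Davies-Bouldin (K=",
              Ks[iDb], ") disagree; using the silhouette choice")
    list(labels = fits[[iSil]]$cluster, K = Ks[iSil], metrics = metrics,
         flagged = flagged, disagreement = iSil != iDb)
  })
}

# ---- regression/classification machinery ----------------------------------

.safeCor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

.splitIdx <- function(n, ratios) {
  idx <- sample.int(n)
  cuts <- round(cumsum(ratios) * n)
  out <- list()
  prev <- 0L
  for (i in seq_along(ratios)) {
    out[[i]] <- idx[(prev + 1L):cuts[i]]
    prev <- cuts[i]
  }
  out
}

# greedy forward selection: add the feature that most improves `objective`
# (a function of selected feature names) until no strict improvement
.forwardSelect <- function(features, objective, minGain = 1e-6) {
  selected <- character(0)
  best <- -Inf
  repeat {
    gains <- vapply(setdiff(features, selected), function(f) {
      objective(c(selected, f))
    }, numeric(1))
    if (length(gains) == 0L) break
    top <- which.max(gains)
    if (gains[top] <= best + minGain) break
    best <- gains[top]
    selected <- c(selected, names(gains)[top])
  }
  list(selected = selected, objective = best)
}

.fitLm <- function(X, y) {
  Xd <- cbind(1, X)
  qr.coef(qr(Xd), y)
}

.predictLm <- function(beta, X) {
  beta[is.na(beta)] <- 0
  as.numeric(cbind(1, X) %*% beta)
}

.xgbParams <- function(hp) {
  list(objective = "reg:squarederror", max_depth = hp$max_depth,
       eta = hp$eta, subsample = hp$subsample,
       colsample_bytree = hp$colsample, nthread = 1L)
}

.fitXgb <- function(X, y, hp) {
  xgboost::xgb.train(params = .xgbParams(hp),
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = hp$nrounds, verbose = 0)
}

.predictXgb <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X))
}

# budgeted random search over the boosted-tree hyperparameter space,
# scored by validation R^2 (sequential model-free stand-in for Bayesian
# optimization at desk scale)
.searchXgbParams <- function(Xtr, ytr, Xval, yval, trials = 20L) {
  best <- NULL
  bestR2 <- -Inf
  for (i in seq_len(trials)) {
    hp <- list(max_depth = sample(2:6, 1L),
               eta = runif(1L, 0.03, 0.3),
               subsample = runif(1L, 0.6, 1),
               colsample = runif(1L, 0.6, 1),
               nrounds = sample(c(40L, 80L, 120L), 1L))
    fit <- .fitXgb(Xtr, ytr, hp)
    pred <- .predictXgb(fit, Xval)
    r2 <- 1 - sum((yval - pred)^2) / sum((yval - mean(yval))^2)
    if (r2 > bestR2) {
      bestR2 <- r2
      best <- hp
    }
  }
  best
}

#' Regression harnesses for a response variable
#'
#' Fits the three model families over \code{cvRepeats} random splits:
#' \itemize{
#'   \item \code{linear}: 60/20/20 train/test/validation split; forward
#'     feature selection maximizing the Pearson correlation on the test
#'     set; validation correlation reported.
#'   \item \code{lasso}: 80/20 split; L1-penalized linear model with the
#'     regularization path selected by internal cross-validation on the
#'     training set; non-zero-coefficient features reported as selected.
#'   \item \code{xgboost}: 60/20/20 split with forward selection on the
#'     test correlation; hyperparameters chosen once by a budgeted random
#'     search scored on validation R-squared of the first split.
#' }
#'
#' @param ft a [FeatureTable-class] or plain numeric matrix
#'   (variants x features).
#' @param y numeric response vector (one per variant).
#' @param cvRepeats number of random-split repeats (default 10).
#' @param seed RNG seed.
#' @param xgbTrials hyperparameter search budget (default 20).
#' @param maxFeatures cap on forward-selection size (default 15).
#' @return list of class \code{"ModelReport"} with per-model elements
#'   \code{repeats} (data.frame repeat/validation_r), \code{selected}
#'   (list of per-repeat feature vectors), and \code{hyperparameters}
#'   (xgboost only).
#' @export
fitRegressors <- function(ft, y, cvRepeats = 10L, seed = 1L,
                          xgbTrials = 20L, maxFeatures = 15L) {
  X <- if (is(ft, "FeatureTable")) featureValues(ft) else as.matrix(ft)
  y <- as.numeric(y)
  .stopIfNot(all(is.finite(X)), "feature matrix contains non-finite values")
  .stopIfNot(all(is.finite(y)), "response contains non-finite values")
  .stopIfNot(nrow(X) >= 30L, "need at least 30 variants to fit")
  n <- nrow(X)
  feats <- colnames(X)

  .withSeed(seed, {
    linRep <- numeric(cvRepeats)
    linSel <- vector("list", cvRepeats)
    xgbRep <- numeric(cvRepeats)
    xgbSel <- vector("list", cvRepeats)
    lasRep <- numeric(cvRepeats)
    lasSel <- vector("list", cvRepeats)

    hpSplit <- .splitIdx(n, c(0.6, 0.2, 0.2))
    hp <- .searchXgbParams(X[hpSplit[[1]], , drop = FALSE], y[hpSplit[[1]]],
                           X[hpSplit[[3]], , drop = FALSE], y[hpSplit[[3]]],
                           trials = xgbTrials)

    for (r in seq_len(cvRepeats)) {
      sp <- .splitIdx(n, c(0.6, 0.2, 0.2))
      tr <- sp[[1]]; te <- sp[[2]]; va <- sp[[3]]

      fsLin <- .forwardSelect(feats, function(sel) {
        if (length(sel) >= length(tr) - 2L || length(sel) > maxFeatures)
          return(-Inf)
        beta <- .fitLm(X[tr, sel, drop = FALSE], y[tr])
        .safeCor(.predictLm(beta, X[te, sel, drop = FALSE]), y[te])
      })
      linSel[[r]] <- fsLin$selected
      linRep[r] <- if (length(fsLin$selected)) {
        beta <- .fitLm(X[tr, fsLin$selected, drop = FALSE], y[tr])
        .safeCor(.predictLm(beta, X[va, fsLin$selected, drop = FALSE]), y[va])
      } else 0

      fsX <- .forwardSelect(feats, function(sel) {
        if (length(sel) > maxFeatures) return(-Inf)
        fit <- .fitXgb(X[tr, sel, drop = FALSE], y[tr], hp)
        .safeCor(.predictXgb(fit, X[te, sel, drop = FALSE]), y[te])
      })
      xgbSel[[r]] <- fsX$selected
      xgbRep[r] <- if (length(fsX$selected)) {
        fit <- .fitXgb(X[tr, fsX$selected, drop = FALSE], y[tr], hp)
        .safeCor(.predictXgb(fit, X[va, fsX$selected, drop = FALSE]), y[va])
      } else 0

      sp2 <- .splitIdx(n, c(0.8, 0.2))
      tr2 <- sp2[[1]]; va2 <- sp2[[2]]
      cvfit <- glmnet::cv.glmnet(X[tr2, , drop = FALSE], y[tr2], nfolds = 5L)
      pred <- as.numeric(predict(cvfit, X[va2, , drop = FALSE],
                                 s = "lambda.min"))
      lasRep[r] <- .safeCor(pred, y[va2])
      cf <- coef(cvfit, s = "lambda.min")
      lasSel[[r]] <- rownames(cf)[-1L][as.numeric(cf)[-1L] != 0]
    }

    structure(list(
      linear = list(model = "linear",
                    repeats = data.frame(rep = seq_len(cvRepeats),
                                         validation_r = linRep),
                    selected = linSel),
      lasso = list(model = "lasso",
                   repeats = data.frame(rep = seq_len(cvRepeats),
                                        validation_r = lasRep),
                   selected = lasSel),
      xgboost = list(model = "xgboost",
                     repeats = data.frame(rep = seq_len(cvRepeats),
                                          validation_r = xgbRep),
                     selected = xgbSel,
                     hyperparameters = hp)),
      class = "ModelReport")
  })
}

#' Three-class thresholds relative to a control value
#'
#' @param maxDiff per-variant maximum net luminescence.
#' @param controlValue the control variant's value.
#' @return list: \code{labels} (integer 0/1/2), \code{thresholds}
#'   (the two tertile boundaries of the control-relative values).
#' @export
classLabels <- function(maxDiff, controlValue) {
  rel <- as.numeric(maxDiff) - controlValue
  thr <- quantile(rel, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (diff(thr) <= 0)
    stop("degenerate tertile thresholds (", format(thr[1]),
         "): too many tied values for a balanced 3-class split")
  labels <- findInterval(rel, thr, left.open = TRUE)
  list(labels = as.integer(labels), thresholds = thr)
}

.fitClassifier <- function(type, X, y, hp = NULL) {
  if (type == "svm") {
    e1071::svm(x = X, y = factor(y, levels = 0:2), kernel = "radial")
  } else {
    params <- list(objective = "multi:softmax", num_class = 3L,
                   max_depth = if (is.null(hp)) 3L else hp$max_depth,
                   eta = if (is.null(hp)) 0.2 else hp$eta, nthread = 1L)
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(X, label = y),
                       nrounds = if (is.null(hp)) 60L else hp$nrounds,
                       verbose = 0)
  }
}

.predictClassifier <- function(type, model, X) {
  if (type == "svm") as.integer(as.character(predict(model, X)))
  else as.integer(predict(model, xgboost::xgb.DMatrix(X)))
}

#' Three-class response classification with permutation validation
#'
#' Variants are labelled into three balanced classes by the tertiles of
#' their control-relative maximum net luminescence, then classified with
#' an RBF-kernel SVM and gradient-boosted trees over \code{cvRepeats}
#' random 80/20 splits with forward feature selection on the held-out
#' accuracy. The permutation null refits the better classifier on
#' \code{nPermutations} label permutations (one split each, using the
#' features selected under the real labels) and records the null
#' accuracies.
#'
#' @param ft [FeatureTable-class] or matrix.
#' @param maxDiff per-variant maximum net luminescence.
#' @param controlValue the control variant's value.
#' @param cvRepeats splits per classifier (default 10).
#' @param nPermutations label permutations for the null (default 100).
#' @param seed RNG seed.
#' @param maxFeatures forward-selection cap (default 10).
#' @return list of class \code{"ClassificationReport"}: \code{labels},
#'   \code{thresholds}, per-model accuracies and selections, \code{null}
#'   (permutation accuracies), \code{best} (model tag used for the null).
#' @export
classifyVariants <- function(ft, maxDiff, controlValue, cvRepeats = 10L,
                             nPermutations = 100L, seed = 1L,
                             maxFeatures = 10L) {
  X <- if (is(ft, "FeatureTable")) featureValues(ft) else as.matrix(ft)
  lab <- classLabels(maxDiff, controlValue)
  y <- lab$labels
  .stopIfNot(min(table(y)) >= 3L, "need at least 3 variants per class")
  n <- nrow(X)
  feats <- colnames(X)

  .withSeed(seed, {
    runModel <- function(type) {
      acc <- numeric(cvRepeats)
      sel <- vector("list", cvRepeats)
      for (r in seq_len(cvRepeats)) {
        sp <- .splitIdx(n, c(0.8, 0.2))
        tr <- sp[[1]]; te <- sp[[2]]
        fs <- .forwardSelect(feats, function(s) {
          if (length(s) > maxFeatures) return(-Inf)
          fit <- .fitClassifier(type, X[tr, s, drop = FALSE], y[tr])
          mean(.predictClassifier(type, fit, X[te, s, drop = FALSE]) == y[te])
        })
        sel[[r]] <- fs$selected
        acc[r] <- fs$objective
      }
      list(accuracy = acc, selected = sel)
    }
    svmRes <- runModel("svm")
    xgbRes <- runModel("xgb")
    best <- if (mean(xgbRes$accuracy) >= mean(svmRes$accuracy)) "xgb" else "svm"
    bestSel <- if (best == "xgb") xgbRes$selected else svmRes$selected
    selFeats <- unique(unlist(bestSel))
    if (length(selFeats) == 0L) selFeats <- feats
    nullAcc <- vapply(seq_len(nPermutations), function(i) {
      yp <- sample(y)
      sp <- .splitIdx(n, c(0.8, 0.2))
      tr <- sp[[1]]; te <- sp[[2]]
      fit <- .fitClassifier(best, X[tr, selFeats, drop = FALSE], yp[tr])
      mean(.predictClassifier(best, fit,
                              X[te, selFeats, drop = FALSE]) == yp[te])
    }, numeric(1))
    structure(list(labels = y, thresholds = lab$thresholds,
                   svm = svmRes, xgboost = xgbRes,
                   best = best, null = nullAcc),
              class = "ClassificationReport")
  })
}

# merge folding windows within `foldRadius` nt and sequence-motif feature
# names one substitution apart; returns a feature -> group-name map
.mergeFeatureNames <- function(features, foldRadius = 10L) {
  map <- setNames(features, features)
  foldIdx <- grepl("^fold_-?\\d+$", features)
  if (any(foldIdx)) {
    nm <- features[foldIdx]
    pos <- as.integer(sub("^fold_", "", nm))
    o <- order(pos)
    grp <- cumsum(c(1L, as.integer(diff(pos[o]) > foldRadius)))
    for (g in unique(grp)) {
      members <- nm[o][grp == g]
      if (length(members) > 1L) {
        gname <- sprintf("fold_%d_%d",
                         min(pos[o][grp == g]), max(pos[o][grp == g]))
        map[members] <- gname
      }
    }
  }
  seqIdx <- grepl("^pssm_[ACGT]+$", features)
  if (sum(seqIdx) > 1L) {
    nm <- features[seqIdx]
    core <- sub("^pssm_", "", nm)
    for (i in seq_along(nm)) {
      for (j in seq_len(i - 1L)) {
        if (nchar(core[i]) == nchar(core[j]) &&
            .hamming(core[i], core[j]) <= 1L)
          map[nm[i]] <- map[nm[j]]
      }
    }
  }
  map
}

#' Feature-importance analysis of a fitted report
#'
#' Produces the three complementary rankings: (1) cross-repeat selection
#' frequency with a top-10% cut (after merging folding windows within 10
#' nt and motif features one substitution apart), (2) the tree-gain
#' ranking of a gradient-boosted fit, and (3) signed additive per-feature
#' attributions (SHAP values; per-variant attributions plus the baseline
#' sum exactly to the model prediction).
#'
#' @param report a \code{ModelReport} (uses its \code{xgboost} component)
#'   or \code{ClassificationReport}.
#' @param ft [FeatureTable-class] or matrix used to fit the report.
#' @param y response used for the final attribution fit.
#' @param foldRadius merge radius for folding windows (nt, default 10).
#' @return list: \code{frequency} (data.frame feature/frequency/top),
#'   \code{gain} (data.frame feature/gain), \code{attribution}
#'   (data.frame feature/mean_attribution/mean_abs_attribution/sign),
#'   \code{attributionMatrix} (variants x features+baseline) and
#'   \code{predictions} (the attribution model's fitted values, whose
#'   row-wise attribution sums they equal).
#' @export
featureImportance <- function(report, ft, y, foldRadius = 10L) {
  X <- if (is(ft, "FeatureTable")) featureValues(ft) else as.matrix(ft)
  y <- as.numeric(y)
  sel <- if (inherits(report, "ClassificationReport")) {
    if (report$best == "xgb") report$xgboost$selected else report$svm$selected
  } else report$xgboost$selected
  nRep <- length(sel)
  map <- .mergeFeatureNames(colnames(X), foldRadius)
  # count each merged group at most once per repeat
  grpPerRep <- lapply(sel, function(s) unique(unname(map[s])))
  cnt <- table(factor(unlist(grpPerRep), levels = unique(map)))
  freq <- setNames(as.numeric(cnt) / nRep, names(cnt))
  ord <- order(-freq, names(freq))
  topK <- max(1L, ceiling(0.10 * length(freq)))
  freqDf <- data.frame(feature = names(freq)[ord],
                       frequency = as.numeric(freq[ord]),
                       top = seq_along(freq) <= topK & freq[ord] > 0,
                       stringsAsFactors = FALSE)

  hp <- list(max_depth = 3L, eta = 0.1, subsample = 1, colsample = 1,
             nrounds = 100L)
  if (!inherits(report, "ClassificationReport") &&
      !is.null(report$xgboost$hyperparameters))
    hp <- report$xgboost$hyperparameters
  fit <- .fitXgb(X, y, hp)
  imp <- xgboost::xgb.importance(model = fit)
  gainDf <- data.frame(feature = imp$Feature, gain = imp$Gain,
                       stringsAsFactors = FALSE)

  contrib <- predict(fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  colnames(contrib) <- c(colnames(X), "baseline")
  attrDf <- data.frame(
    feature = colnames(X),
    mean_attribution = colMeans(contrib[, colnames(X), drop = FALSE]),
    mean_abs_attribution = colMeans(abs(contrib[, colnames(X), drop = FALSE])),
    stringsAsFactors = FALSE)
  attrDf$sign <- sign(attrDf$mean_attribution)
  attrDf <- attrDf[order(-attrDf$mean_abs_attribution), ]
  rownames(attrDf) <- NULL
  list(frequency = freqDf, gain = gainDf, attribution = attrDf,
       attributionMatrix = contrib,
       predictions = predict(fit, xgboost::xgb.DMatrix(X)))
}

#' Per-variant significance against the control with a randomization FDR
#'
#' Each variant's replicate values are compared with the control's by a
#' Welch two-sample t-test. The false-discovery estimate follows the
#' randomization recipe: all values are pooled and reassigned at random
#' to the same variant/control structure \code{nRandom} times, and
#' FDR = mean(significant count under randomization) / observed
#' significant count.
#'
#' @param values data.frame with columns \code{variant_id}, \code{value}
#'   (one row per replicate), including the control's replicates.
#' @param controlId id of the control variant (default \code{"control"}).
#' @param nRandom randomized datasets (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return list: \code{perVariant} (data.frame variant_id/p/significant/
#'   flag), \code{nSignificant}, \code{fdr}, \code{nullCounts}.
#' @export
variantSignificance <- function(values, controlId = "control",
                                nRandom = 100L, alpha = 0.05, seed = 1L) {
  .stopIfNot(controlId %in% values$variant_id,
             "control id '%s' not present", controlId)
  ctrl <- values$value[values$variant_id == controlId]
  .stopIfNot(length(ctrl) >= 2L, "control needs >= 2 replicates")
  ids <- setdiff(unique(values$variant_id), controlId)

  testOne <- function(v, ctrl) {
    if (length(v) < 2L) return(c(NA_real_, 1))
    if (sd(v) == 0 && sd(ctrl) == 0) return(c(NA_real_, 2))
    c(t.test(v, ctrl)$p.value, 0)
  }
  res <- t(vapply(ids, function(id) {
    testOne(values$value[values$variant_id == id], ctrl)
  }, numeric(2)))
  perVariant <- data.frame(
    variant_id = ids, p = res[, 1L],
    significant = !is.na(res[, 1L]) & res[, 1L] < alpha,
    flag = c("ok", "too_few_replicates", "zero_variance")[res[, 2L] + 1L],
    stringsAsFactors = FALSE)
  obs <- sum(perVariant$significant)

  .withSeed(seed, {
    nullCounts <- vapply(seq_len(nRandom), function(i) {
      shuffled <- sample(values$value)
      ctrlS <- shuffled[values$variant_id == controlId]
      sum(vapply(ids, function(id) {
        r <- testOne(shuffled[values$variant_id == id], ctrlS)
        !is.na(r[1L]) && r[1L] < alpha
      }, logical(1)))
    }, numeric(1))
    list(perVariant = perVariant, nSignificant = obs,
         fdr = if (obs > 0) mean(nullCounts) / obs else NA_real_,
         nullCounts = nullCounts)
  })
}

#' EC200: concentration doubling the uninduced signal
#'
#' Finds the smallest inducer concentration at which the induced/uninduced
#' luminescence ratio reaches 2. An exact hit returns that dose; otherwise
#' the crossing is interpolated with log(ratio) linear in
#' log10(concentration) between the bracketing doses. If the curve crosses
#' 2 more than once the first crossing is used with a warning.
#'
#' @param dose concentrations (mg/l), any order.
#' @param ratio matching induced/uninduced ratios (positive).
#' @return list: \code{ec200} (mg/l, \code{NA_real_} if the ratio never
#'   reaches 2), \code{reached} (logical).
#' @export
computeEC200 <- function(dose, ratio) {
  .stopIfNot(length(dose) == length(ratio), "dose and ratio lengths differ")
  .stopIfNot(length(dose) >= 2L, "need at least two doses")
  .stopIfNot(all(ratio > 0) && all(dose > 0), "doses and ratios must be positive")
  o <- order(dose)
  dose <- dose[o]
  ratio <- ratio[o]
  if (any(ratio == 2))
    return(list(ec200 = dose[which(ratio == 2)[1L]], reached = TRUE))
  if (max(ratio) < 2) return(list(ec200 = NA_real_, reached = FALSE))
  cross <- which(ratio[-length(ratio)] < 2 & ratio[-1L] > 2)
  if (ratio[1L] > 2) {
    warning("ratio already above 2 at the lowest dose; EC200 left-censored")
    return(list(ec200 = dose[1L], reached = TRUE))
  }
  if (length(cross) > 1L)
    warning("non-monotone dose-response: first crossing of 2 used")
  i <- cross[1L]
  f <- (log(2) - log(ratio[i])) / (log(ratio[i + 1L]) - log(ratio[i]))
  ld <- log10(dose[i]) + f * (log10(dose[i + 1L]) - log10(dose[i]))
  list(ec200 = 10^ld, reached = TRUE)
}
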