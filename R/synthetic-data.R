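# Seeded generators that produce every pipeline input with planted ground
# truth: an endogenous two-condition expression set, a flow-seq mutagenesis
# library sorted into logarithmic fluorescence bins, and luminescence time
# courses driven by known sequence features.

#' Planted ground truth for the synthetic generators
#'
#' @param consensus planted motif consensus (default an 8-mer of high
#'   information content).
#' @param position anchored coordinate of the planted site (default -120).
#' @param effect expression effect of carrying the motif, in units of the
#'   between-replicate noise SD (default 5).
#' @param subRate per-site substitution noise applied to planted sites
#'   (default 0.1).
#' @param overFraction,underFraction fractions of records designated as
#'   motif-carrying over-expressed and (counter-)under-expressed
#'   (defaults 0.10 each).
#' @param composition background base probabilities (A, C, G, T); default
#'   uniform, with an AT-rich E. coli-like alternative available via
#'   \code{composition = c(.3, .2, .2, .3)}.
#' @param seed integer seed stored with the truth object.
#' @return list of class \code{"GroundTruth"}.
#' @export
groundTruth <- function(consensus = "TGACCTTA", position = -120L,
                        effect = 5, subRate = 0.1,
                        overFraction = 0.10, underFraction = 0.10,
                        composition = rep(0.25, 4), seed = 1L) {
  .stopIfNot(abs(sum(composition) - 1) < 1e-9,
             "composition must sum to 1")
  structure(list(consensus = toupper(consensus),
                 position = as.integer(position),
                 effect = effect, subRate = subRate,
                 overFraction = overFraction,
                 underFraction = underFraction,
                 composition = composition, seed = as.integer(seed)),
            class = "GroundTruth")
}

#' Write / read a GroundTruth as JSON
#'
#' @param gt a \code{GroundTruth}.
#' @param path JSON file.
#' @return \code{writeGroundTruth}: invisibly, \code{path};
#'   \code{readGroundTruth}: the \code{GroundTruth}.
#' @export
writeGroundTruth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(groundTruth, x[setdiff(names(x), character(0))])
}

.randomSeq <- function(len, composition = rep(0.25, 4)) {
  paste(sample(DNA_BASES, len, replace = TRUE, prob = composition),
        collapse = "")
}

# plant `site` at 1-based index `at`, with per-base substitution noise
.plantSite <- function(seq, site, at, subRate) {
  chars <- stri_sub(seq, seq_len(nchar(seq)), length = 1L)
  sChars <- stri_sub(site, seq_len(nchar(site)), length = 1L)
  noise <- runif(length(sChars)) < subRate
  if (any(noise))
    sChars[noise] <- vapply(sChars[noise], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
  chars[at:(at + length(sChars) - 1L)] <- sChars
  paste(chars, collapse = "")
}

#' Generate a synthetic endogenous expression dataset
#'
#' Background promoters are i.i.d. under the configured base composition.
#' A designated over-expressed subset (fraction \code{gt$overFraction})
#' carries the planted consensus (with per-site substitution noise) at the
#' planted coordinate and receives the planted positive expression shift
#' under exposure; a designated under-expressed subset receives the
#' negative shift (without a planted site). Expression is
#' baseline + effect * carrier + Gaussian noise.
#'
#' @param nGenes number of genes (default 500).
#' @param promoterLen promoter length in nt (default 400).
#' @param gt a [groundTruth()] object.
#' @param seed RNG seed.
#' @param baseline,betweenSd mean and between-gene SD of the control
#'   expression (defaults 100, 10).
#' @param deltaSd SD of the exposure-induced noise on delta (default 1).
#' @return data.frame: \code{gene_id}, \code{sequence}, \code{expr_dnt},
#'   \code{expr_ctrl}, \code{delta}, \code{carrier}, \code{suppressed};
#'   attribute \code{"truth"}.
#' @export
genDatasetA <- function(nGenes = 500L, promoterLen = 400L, gt = groundTruth(),
                        seed = gt$seed, baseline = 100, betweenSd = 10,
                        deltaSd = 1) {
  at <- unanchorCoord(gt$position, promoterLen)
  .stopIfNot(at >= 1L && at + nchar(gt$consensus) - 1L <= promoterLen,
             "planted position %d outside the promoter", gt$position)
  .withSeed(seed, {
    nOver <- as.integer(ceiling(gt$overFraction * nGenes))
    nUnder <- as.integer(ceiling(gt$underFraction * nGenes))
    carrier <- rep(FALSE, nGenes)
    suppressed <- rep(FALSE, nGenes)
    carrier[sample.int(nGenes, nOver)] <- TRUE
    suppressed[sample(which(!carrier), nUnder)] <- TRUE
    seqs <- vapply(seq_len(nGenes), function(i) {
      s <- .randomSeq(promoterLen, gt$composition)
      if (carrier[i]) s <- .plantSite(s, gt$consensus, at, gt$subRate)
      s
    }, character(1))
    exprCtrl <- rnorm(nGenes, baseline, betweenSd)
    shift <- gt$effect * deltaSd * (carrier - suppressed)
    exprDnt <- exprCtrl + shift + rnorm(nGenes, 0, deltaSd)
    out <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(nGenes)),
      sequence = seqs, expr_dnt = exprDnt, expr_ctrl = exprCtrl,
      delta = exprDnt - exprCtrl, carrier = carrier,
      suppressed = suppressed, stringsAsFactors = FALSE)
    attr(out, "truth") <- gt
    out
  })
}

#' Generate a synthetic flow-seq mutagenesis library
#'
#' Variants of a base promoter carry 1..\code{maxOrder} substitutions at
#' \code{nSites} designated sites; a designated fraction additionally
#' carries the planted consensus (substituted in at the planted
#' coordinate). Log-fluorescence is a linear model over per-site effects
#' plus noise; under the exposed condition, motif carriers are multiplied
#' by \code{dntMultiplier}. Each variant's reads are multinomial over 16
#' logarithmically spaced bins centred on its log-fluorescence.
#'
#' @param basePromoter base sequence; generated at random (length
#'   \code{baseLen}) when NULL.
#' @param nVariants library size (default 2000).
#' @param gt a [groundTruth()]; \code{gt$position} must fit the promoter.
#' @param seed RNG seed.
#' @param baseLen base promoter length when generated (default 200).
#' @param nSites number of mutable sites (default 147).
#' @param maxOrder maximum substitutions per variant (default 3).
#' @param bins number of fluorescence bins (default 16).
#' @param depth reads per variant per condition (default 200).
#' @param carrierFraction fraction of variants carrying the planted motif
#'   (default 0.15).
#' @param siteEffectSd SD of per-site log-fluorescence effects (default 0.2).
#' @param noiseSd log-fluorescence noise SD (default 0.1).
#' @param dntMultiplier fluorescence multiplier for carriers under
#'   exposure (default 4).
#' @param binSd multinomial spread of reads across bins, in log10
#'   fluorescence units (default 0.25).
#' @return list: \code{records} (bin-count data.frame, both conditions),
#'   \code{sequences} (named character), \code{binMeans}, \code{truth}
#'   (the \code{GroundTruth}), \code{carriers} (logical), \code{trueF}
#'   (control-condition fluorescence).
#' @export
genDatasetB <- function(basePromoter = NULL, nVariants = 2000L,
                        gt = groundTruth(), seed = gt$seed, baseLen = 200L,
                        nSites = 147L, maxOrder = 3L, bins = 16L,
                        depth = 200L, carrierFraction = 0.15,
                        siteEffectSd = 0.2, noiseSd = 0.1,
                        dntMultiplier = 4, binSd = 0.25) {
  .stopIfNot(depth > 0, "sequencing depth must be positive")
  .withSeed(seed, {
    if (is.null(basePromoter))
      basePromoter <- .randomSeq(baseLen, gt$composition)
    len <- nchar(basePromoter)
    at <- unanchorCoord(gt$position, len)
    .stopIfNot(at >= 1L && at + nchar(gt$consensus) - 1L <= len,
               "planted position %d outside the base promoter", gt$position)
    sites <- sort(sample.int(len, min(nSites, len)))
    siteEffect <- rnorm(length(sites), 0, siteEffectSd)
    carriers <- runif(nVariants) < carrierFraction
    baseChars <- stri_sub(basePromoter, seq_len(len), length = 1L)
    seqs <- character(nVariants)
    logF <- numeric(nVariants)
    for (i in seq_len(nVariants)) {
      chars <- baseChars
      k <- sample.int(maxOrder, 1L)
      mutAt <- sample(sites, k)
      for (m in mutAt)
        chars[m] <- sample(setdiff(DNA_BASES, chars[m]), 1L)
      s <- paste(chars, collapse = "")
      eff <- sum(siteEffect[match(mutAt, sites)])
      if (carriers[i]) s <- .plantSite(s, gt$consensus, at, gt$subRate)
      seqs[i] <- s
      logF[i] <- 3 + eff + rnorm(1L, 0, noiseSd)
    }
    ids <- sprintf("var%05d", seq_len(nVariants))
    names(seqs) <- ids
    fCtrl <- 10^logF
    fDnt <- fCtrl * ifelse(carriers, dntMultiplier, 1)
    binMeans <- 10^seq(1, 5, length.out = bins)
    drawCounts <- function(f) {
      pr <- stats::dnorm(log10(binMeans), log10(f), binSd)
      if (sum(pr) == 0) pr <- rep(1, bins)
      as.integer(stats::rmultinom(1L, depth, pr))
    }
    recs <- rbind(
      data.frame(variant_id = ids, condition = "DNT",
                 t(vapply(fDnt, drawCounts, integer(bins))),
                 stringsAsFactors = FALSE),
      data.frame(variant_id = ids, condition = "control",
                 t(vapply(fCtrl, drawCounts, integer(bins))),
                 stringsAsFactors = FALSE))
    names(recs)[3:(2 + bins)] <- paste0("n_", seq_len(bins))
    rownames(recs) <- NULL
    list(records = recs, sequences = seqs, binMeans = binMeans,
         truth = gt, carriers = carriers, trueF = fCtrl,
         basePromoter = basePromoter)
  })
}

#' Generate synthetic luminescence time courses
#'
#' The net signal of each variant is
#' delta(t) = amplitude * logistic((t - onset) / rate) + noise, with the
#' amplitude a linear function of designated true features:
#' amplitude = intercept + X w. The control variant gets the intercept
#' alone. Two replicates per variant by default; the logistic shape
#' reproduces the sigmoidal signal development of reporter assays, with
#' the onset parameter controlling the response lag.
#'
#' @param features numeric matrix (variants x features, rownames = ids).
#' @param weights named weight vector over a subset of the feature
#'   columns (the designated true features).
#' @param timegrid time points in hours (default 0:10).
#' @param seed RNG seed.
#' @param intercept control amplitude (default 100).
#' @param onset response onset time in hours (default 2.5).
#' @param rate logistic rise time constant in hours (default 1).
#' @param noiseSd measurement noise SD in RLU (default 5).
#' @param baselineLum uninduced luminescence level (default 50).
#' @param replicates replicates per variant (default 2).
#' @param controlId id given to the appended control rows
#'   (default \code{"control"}; set NULL to skip).
#' @return luminescence data.frame (\code{variant_id}, \code{replicate},
#'   \code{time}, \code{lum_dnt}, \code{lum_ctrl}); attribute
#'   \code{"amplitudes"}.
#' @export
genLuminescence <- function(features, weights, timegrid = 0:10, seed = 1L,
                            intercept = 100, onset = 2.5, rate = 1,
                            noiseSd = 5, baselineLum = 50, replicates = 2L,
                            controlId = "control") {
  .stopIfNot(all(names(weights) %in% colnames(features)),
             "weights name features absent from the matrix")
  amp <- intercept + as.numeric(features[, names(weights), drop = FALSE] %*%
                                  weights)
  names(amp) <- rownames(features)
  if (!is.null(controlId) && !(controlId %in% names(amp)))
    amp <- c(setNames(intercept, controlId), amp)
  shape <- stats::plogis((timegrid - onset) / rate)
  .withSeed(seed, {
    rows <- list()
    for (id in names(amp)) {
      for (r in seq_len(replicates)) {
        ctrl <- baselineLum + rnorm(length(timegrid), 0, noiseSd)
        dnt <- ctrl + amp[[id]] * shape + rnorm(length(timegrid), 0, noiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = id, replicate = r, time = timegrid,
          lum_dnt = dnt, lum_ctrl = ctrl, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "amplitudes") <- amp
    out
  })
}
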