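# Sequence-feature extraction for promoter variants. Folding features use
# the nearest-neighbor minimum-free-energy model via the ViennaRNA RNAfold
# program (the promoter DNA sequence is folded under RNA rules, T read as
# U); anti-Shine-Dalgarno hybridization uses RNAduplex.

.viennaBin <- function(tool) {
  p <- Sys.which(tool)
  if (p == "")
    stop("the ViennaRNA program '", tool, "' is required but not on PATH")
  p
}

#' Minimum free energy of sequences (nearest-neighbor model)
#'
#' Batch MFE prediction via RNAfold; one external process for the whole
#' vector.
#'
#' @param seqs character vector of sequences (A/C/G/T; T is folded as U).
#' @return numeric vector of MFE values (kcal/mol), 0 for unpairable
#'   sequences.
#' @export
rnaFoldMFE <- function(seqs) {
  if (length(seqs) == 0L) return(numeric(0))
  out <- system2(.viennaBin("RNAfold"), c("--noPS"),
                 input = as.character(seqs), stdout = TRUE)
  elines <- grep("\\(\\s*-?[0-9.]+\\)\\s*$", out, value = TRUE)
  .stopIfNot(length(elines) == length(seqs),
             "RNAfold returned %d records for %d sequences",
             length(elines), length(seqs))
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", elines))
}

#' Folding-energy profile of a promoter
#'
#' MFE is computed for every window of \code{window} nt advancing by
#' \code{step} (the window position is the anchored coordinate of its
#' first nucleotide), along with the mean over windows and the MFE of the
#' whole sequence. Sequences shorter than the window yield no window
#' features but still report the whole-sequence value.
#'
#' @param seq promoter sequence string.
#' @param window window size in nt (default 40).
#' @param step window step in nt (default 1).
#' @return list: \code{windows} (data.frame position/mfe), \code{average},
#'   \code{total}.
#' @export
foldingProfile <- function(seq, window = 40L, step = 1L) {
  len <- nchar(seq)
  total <- rnaFoldMFE(seq)
  if (len < window)
    return(list(windows = data.frame(position = integer(0), mfe = numeric(0)),
                average = NA_real_, total = total))
  starts <- seq.int(1L, len - window + 1L, by = step)
  mfe <- rnaFoldMFE(stri_sub(seq, starts, length = window))
  list(windows = data.frame(position = anchorCoord(starts, len), mfe = mfe),
       average = mean(mfe), total = total)
}

#' Per-position mutation indicators against a control
#'
#' @param variant,control equal-length sequence strings.
#' @return list: \code{vector} (named 0/1 integer vector over anchored
#'   coordinates), \code{count}.
#' @export
mutationFeatures <- function(variant, control) {
  .stopIfNot(nchar(variant) == nchar(control),
             "variant (%d nt) and control (%d nt) lengths differ",
             nchar(variant), nchar(control))
  len <- nchar(control)
  v <- as.integer(stri_sub(variant, seq_len(len), length = 1L) !=
                  stri_sub(control, seq_len(len), length = 1L))
  names(v) <- anchorCoord(seq_len(len), len)
  list(vector = v, count = sum(v))
}

#' ChimeraARS: average repetitive substring index
#'
#' For every start position p of \code{seq}, the length of the longest
#' substring starting at p that occurs anywhere in the reference set; the
#' index is the mean over positions (0 where not even the single base
#' matches).
#'
#' @param seq query sequence string.
#' @param reference character vector of reference sequences.
#' @return average longest-match length.
#' @export
chimeraARS <- function(seq, reference) {
  .stopIfNot(length(reference) > 0, "reference set must be non-empty")
  n <- nchar(seq)
  refcat <- paste(reference, collapse = "|")
  lens <- integer(n)
  for (p in seq_len(n)) {
    # warm start: a match of length l at p-1 guarantees >= l-1 here
    l <- if (p > 1L) max(lens[p - 1L] - 1L, 0L) else 0L
    while (p + l <= n &&
           stri_detect_fixed(refcat, stri_sub(seq, p, length = l + 1L))) {
      l <- l + 1L
    }
    lens[p] <- l
  }
  mean(lens)
}

#' Maximum PSSM score features
#'
#' One feature per motif: the maximum sliding-window score of the motif
#' along the sequence. Motifs longer than the sequence are omitted with a
#' warning.
#'
#' @param seq sequence string.
#' @param motifs list of [PSSM-class].
#' @return named numeric vector (names = motif names).
#' @export
motifScoreFeatures <- function(seq, motifs) {
  keep <- vapply(motifs, function(m) motifLength(m) <= nchar(seq), logical(1))
  if (any(!keep))
    warning(sum(!keep), " motif(s) longer than the sequence omitted")
  out <- vapply(motifs[keep], function(m) {
    max(slidingScores(m, seq)$score)
  }, numeric(1))
  names(out) <- vapply(motifs[keep], motifName, character(1))
  out
}

#' Promoter strength from a position energy matrix
#'
#' The energy matrix (4 x 41, kBT) covers anchored offsets -41..-1
#' relative to the transcription start site; the contribution of offset o
#' is matrix[base at tss+o, o], and the total/average are the sum/mean of
#' the 41 contributions.
#'
#' @param seq sequence string.
#' @param matrix 4 x 41 numeric matrix, rows A,C,G,T, columns offsets
#'   -41..-1 (as from [readEnergyMatrix()]).
#' @param tss anchored coordinate of the transcription start site.
#' @return list: \code{perPosition} (named 41-vector), \code{total},
#'   \code{average}.
#' @export
promoterStrength <- function(seq, matrix, tss) {
  .stopIfNot(ncol(matrix) == 41L, "energy matrix must have 41 columns")
  len <- nchar(seq)
  offsets <- -41:-1
  coords <- tss + offsets
  idx <- unanchorCoord(coords, len)
  .stopIfNot(all(idx >= 1L & idx <= len),
             "strength window [tss-41, tss-1] falls outside the sequence")
  bases <- match(stri_sub(seq, idx, length = 1L), DNA_BASES)
  contrib <- matrix[cbind(bases, seq_along(offsets))]
  names(contrib) <- offsets
  list(perPosition = contrib, total = sum(contrib), average = mean(contrib))
}

ASD_CORE <- "ACCUCCUUA"  # 16S rRNA 3' tail (anti-Shine-Dalgarno), 5'->3'

#' Nucleotide composition and ribosome-binding-site strength features
#'
#' Composition: mono- and dinucleotide counts and frequencies plus GC
#' content. RBS strength: for every 6-nt window along the sequence, the
#' hybridization free energy of the window (read as RNA) against the
#' anti-Shine-Dalgarno core, from the nearest-neighbor duplex model
#' (RNAduplex); windows that cannot pair get 0.
#'
#' @param seq sequence string (length >= 6 for RBS features).
#' @param asd anti-Shine-Dalgarno core sequence (RNA alphabet).
#' @param rbsWindow RBS window size in nt (default 6).
#' @return list: \code{composition} (named numeric vector),
#'   \code{rbs} (data.frame position/energy).
#' @export
compositionAndRbs <- function(seq, asd = ASD_CORE, rbsWindow = 6L) {
  len <- nchar(seq)
  chars <- stri_sub(seq, seq_len(len), length = 1L)
  mono <- vapply(DNA_BASES, function(b) sum(chars == b), numeric(1))
  names(mono) <- paste0("count_", DNA_BASES)
  monoFreq <- mono / len
  names(monoFreq) <- paste0("freq_", DNA_BASES)
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  di <- if (len >= 2L) {
    pairs <- paste0(chars[-len], chars[-1L])
    vapply(dinucs, function(d) sum(pairs == d), numeric(1))
  } else stats::setNames(numeric(16L), dinucs)
  names(di) <- paste0("count_", dinucs)
  diFreq <- if (len >= 2L) di / (len - 1L) else di
  names(diFreq) <- paste0("freq_", dinucs)
  gc <- unname((mono["count_G"] + mono["count_C"]) / len)
  composition <- c(mono, monoFreq, di, diFreq, GC = gc)

  rbs <- data.frame(position = integer(0), energy = numeric(0))
  if (len >= rbsWindow) {
    starts <- seq_len(len - rbsWindow + 1L)
    wins <- stri_sub(seq, starts, length = rbsWindow)
    inp <- as.vector(rbind(wins, asd))
    out <- system2(.viennaBin("RNAduplex"), character(0), input = inp,
                   stdout = TRUE, stderr = FALSE)
    evals <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
    .stopIfNot(length(evals) == length(wins),
               "RNAduplex returned %d records for %d windows",
               length(evals), length(wins))
    en <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", evals))
    en[!is.finite(en)] <- 0
    rbs <- data.frame(position = anchorCoord(starts, len), energy = en)
  }
  list(composition = composition, rbs = rbs)
}

#' Reduce redundant features
#'
#' Applies the two redundancy rules: (1) folding features are greedily
#' grouped by absolute Spearman correlation above \code{spearmanCutoff}
#' and only the first (left-most window) representative of each group is
#' kept; (2) mutation-indicator features at adjacent coordinates (within
#' 1 nt) are averaged into a single profile feature. Constant features
#' (undefined correlation) are kept and flagged. Other categories are
#' untouched.
#'
#' @param ft a [FeatureTable-class] (needs >= 2 variants).
#' @param spearmanCutoff redundancy cutoff (default 0.99).
#' @return list: \code{table} (reduced [FeatureTable-class]),
#'   \code{dropped} (folding features removed), \code{constant} (flagged
#'   constant folding features), \code{merged} (mutation merge map).
#' @export
reduceFeatures <- function(ft, spearmanCutoff = 0.99) {
  vals <- featureValues(ft)
  meta <- featureMeta(ft)
  .stopIfNot(nrow(vals) >= 2L, "feature reduction needs >= 2 variants")

  foldIdx <- which(meta$category == "folding")
  dropped <- character(0)
  constant <- character(0)
  if (length(foldIdx) >= 2L) {
    sub <- vals[, foldIdx, drop = FALSE]
    sds <- apply(sub, 2L, stats::sd)
    constant <- colnames(sub)[sds == 0]
    rho <- suppressWarnings(stats::cor(sub, method = "spearman"))
    keepNames <- character(0)
    for (nm in colnames(sub)) {
      if (sds[nm] == 0) { keepNames <- c(keepNames, nm); next }
      dup <- any(vapply(keepNames, function(k) {
        r <- rho[nm, k]
        is.finite(r) && abs(r) > spearmanCutoff
      }, logical(1)))
      if (dup) dropped <- c(dropped, nm) else keepNames <- c(keepNames, nm)
    }
    keepCols <- setdiff(colnames(vals), dropped)
    vals <- vals[, keepCols, drop = FALSE]
    meta <- meta[meta$feature %in% keepCols, , drop = FALSE]
  }

  mutIdx <- which(meta$category == "mutation" &
                  grepl("^mut_-?\\d+$", meta$feature))
  merged <- list()
  if (length(mutIdx) >= 2L) {
    mutNames <- meta$feature[mutIdx]
    coords <- as.integer(sub("^mut_", "", mutNames))
    ord <- order(coords)
    mutNames <- mutNames[ord]
    coords <- coords[ord]
    grp <- cumsum(c(1L, as.integer(diff(coords) > 1L)))
    newCols <- list()
    for (g in unique(grp)) {
      nms <- mutNames[grp == g]
      if (length(nms) == 1L) next
      newName <- sprintf("mut_%d_%d", min(coords[grp == g]),
                         max(coords[grp == g]))
      newCols[[newName]] <- rowMeans(vals[, nms, drop = FALSE])
      merged[[newName]] <- nms
    }
    if (length(newCols)) {
      oldMerged <- unlist(merged, use.names = FALSE)
      keepCols <- setdiff(colnames(vals), oldMerged)
      vals <- cbind(vals[, keepCols, drop = FALSE],
                    do.call(cbind, newCols))
      meta <- rbind(meta[meta$feature %in% keepCols, , drop = FALSE],
                    data.frame(feature = names(newCols),
                               category = "mutation",
                               stringsAsFactors = FALSE))
    }
  }
  meta <- meta[match(colnames(vals), meta$feature), ]
  rownames(meta) <- NULL
  list(table = new("FeatureTable", values = vals, meta = meta),
       dropped = dropped, constant = constant, merged = merged)
}

#' Extract the full feature table for a variant set
#'
#' Assembles mutation, ChimeraARS, motif-score, promoter-strength,
#' composition, RBS-window and (optionally) folding-window features into
#' one [FeatureTable-class]. Extraction is a pure function of its inputs:
#' identical sequences and catalogs give bit-identical tables.
#'
#' @param seqs named character vector of variant sequences (equal length).
#' @param control control sequence (same length), used for mutation
#'   features.
#' @param motifs optional list of [PSSM-class] for motif-score features.
#' @param energyMatrix optional 4 x 41 matrix for promoter strength.
#' @param tss anchored TSS coordinate for the strength window (default -1,
#'   i.e. the strength window is the 41 nt closest to the start codon).
#' @param chimeraReference optional reference sequence set for ChimeraARS.
#' @param includeFolding compute per-window folding features (slow;
#'   default TRUE).
#' @param window,step folding window size and step.
#' @param rbsWindow RBS window size.
#' @return a [FeatureTable-class].
#' @export
extractFeatures <- function(seqs, control, motifs = NULL,
                            energyMatrix = NULL, tss = -1L,
                            chimeraReference = NULL,
                            includeFolding = TRUE, window = 40L, step = 1L,
                            rbsWindow = 6L) {
  .stopIfNot(!is.null(names(seqs)), "variant sequences must be named")
  ids <- names(seqs)
  tabs <- list()

  mut <- lapply(seqs, mutationFeatures, control = control)
  mutMat <- do.call(rbind, lapply(mut, function(m) m$vector))
  colnames(mutMat) <- paste0("mut_", names(mut[[1L]]$vector))
  mutMat <- cbind(mutMat, mut_total = vapply(mut, `[[`, numeric(1), "count"))
  rownames(mutMat) <- ids
  tabs[[length(tabs) + 1L]] <- featureTable(mutMat, "mutation")

  if (!is.null(chimeraReference)) {
    ch <- matrix(vapply(seqs, chimeraARS, numeric(1),
                        reference = chimeraReference), ncol = 1L,
                 dimnames = list(ids, "chimera_ars"))
    tabs[[length(tabs) + 1L]] <- featureTable(ch, "chimera")
  }

  if (!is.null(motifs) && length(motifs)) {
    fits <- vapply(motifs, function(m)
      motifLength(m) <= min(nchar(seqs)), logical(1))
    if (any(!fits))
      warning(sum(!fits), " motif(s) longer than the variants omitted")
    motifs <- motifs[fits]
  }
  if (!is.null(motifs) && length(motifs)) {
    ms <- vapply(seqs, motifScoreFeatures, numeric(length(motifs)),
                 motifs = motifs)
    ms <- if (is.null(dim(ms))) matrix(ms, ncol = 1L) else t(ms)
    colnames(ms) <- paste0("pssm_", vapply(motifs, motifName, character(1)))
    rownames(ms) <- ids
    tabs[[length(tabs) + 1L]] <- featureTable(ms, "motif_pssm")
  }

  if (!is.null(energyMatrix)) {
    st <- lapply(seqs, promoterStrength, matrix = energyMatrix, tss = tss)
    stMat <- do.call(rbind, lapply(st, function(s) s$perPosition))
    colnames(stMat) <- paste0("strength_", -41:-1)
    stMat <- cbind(stMat,
                   strength_total = vapply(st, `[[`, numeric(1), "total"),
                   strength_avg = vapply(st, `[[`, numeric(1), "average"))
    rownames(stMat) <- ids
    tabs[[length(tabs) + 1L]] <- featureTable(stMat, "strength")
  }

  cr <- lapply(seqs, compositionAndRbs, rbsWindow = rbsWindow)
  compMat <- do.call(rbind, lapply(cr, `[[`, "composition"))
  rownames(compMat) <- ids
  tabs[[length(tabs) + 1L]] <- featureTable(compMat, "composition")
  rbsMat <- do.call(rbind, lapply(cr, function(x) x$rbs$energy))
  if (ncol(rbsMat) > 0L) {
    colnames(rbsMat) <- paste0("rbs_", cr[[1L]]$rbs$position)
    rownames(rbsMat) <- ids
    tabs[[length(tabs) + 1L]] <- featureTable(rbsMat, "rbs")
  }

  if (includeFolding) {
    fp <- lapply(seqs, foldingProfile, window = window, step = step)
    foldMat <- do.call(rbind, lapply(fp, function(f) f$windows$mfe))
    if (ncol(foldMat) > 0L) {
      colnames(foldMat) <- paste0("fold_", fp[[1L]]$windows$position)
      foldMat <- cbind(foldMat,
                       fold_avg = vapply(fp, `[[`, numeric(1), "average"),
                       fold_total = vapply(fp, `[[`, numeric(1), "total"))
      rownames(foldMat) <- ids
      tabs[[length(tabs) + 1L]] <- featureTable(foldMat, "folding")
    }
  }
  do.call(cbindFeatureTables, tabs)
}

#' Write a feature table and its metadata sidecar
#'
#' @param ft a [FeatureTable-class].
#' @param valuesPath TSV for the matrix (first column \code{variant_id}).
#' @param metaPath TSV for the feature/category sidecar.
#' @return invisibly, the two paths.
#' @export
writeFeatureTable <- function(ft, valuesPath, metaPath) {
  df <- data.frame(variant_id = rownames(featureValues(ft)),
                   featureValues(ft), check.names = FALSE)
  .writeTsv(df, valuesPath)
  .writeTsv(featureMeta(ft), metaPath)
  invisible(c(valuesPath, metaPath))
}
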