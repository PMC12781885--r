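# Positional analysis: permutation-significant motif sites, prevalence
# windows, cross-dataset harmonization, and the insertion/removal decision.

#' Permutation-significant motif positions in a promoter
#'
#' The promoter is shuffled \code{nPerm} times (mononucleotide permutation,
#' composition-preserving) and the motif is scored at every position of
#' every shuffle. The per-position empirical p compares the observed score
#' with the null scores *at the same position* across shuffles (ties count
#' toward the null); positions with p <= alpha are reported as hits.
#'
#' @param pssm a [PSSM-class].
#' @param promoter promoter sequence string.
#' @param id promoter identifier carried into the result.
#' @param nPerm number of shuffles (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed optional RNG seed.
#' @return list with \code{hits} (data.frame motif/promoter_id/position/
#'   score/p for significant positions) and \code{profile} (all positions).
#' @export
significantPositions <- function(pssm, promoter, id = "promoter",
                                 nPerm = 100L, alpha = 0.05, seed = NULL) {
  L <- motifLength(pssm)
  len <- nchar(promoter)
  .stopIfNot(len >= L, "promoter '%s' is shorter than the motif", id)
  si <- .seqToInt(promoter, id)
  lo <- .logOdds(pssm)
  real <- .slideInt(lo, si)
  .withSeed(seed, {
    geCount <- numeric(length(real))
    for (k in seq_len(nPerm)) {
      nullSc <- .slideInt(lo, sample(si))
      geCount <- geCount + (nullSc >= real)
    }
    p <- geCount / nPerm
    idx <- seq_along(real)
    profile <- data.frame(motif = motifName(pssm), promoter_id = id,
                          index = idx, position = anchorCoord(idx, len),
                          score = real, p = p, stringsAsFactors = FALSE)
    list(hits = profile[profile$p <= alpha, , drop = FALSE],
         profile = profile)
  })
}

#' Hits for one motif across a set of promoters
#'
#' @param pssm a [PSSM-class].
#' @param promoters named character vector of sequences.
#' @param ... passed to [significantPositions()].
#' @return data.frame of hits (all promoters pooled).
#' @export
collectHits <- function(pssm, promoters, ...) {
  out <- lapply(names(promoters), function(id) {
    significantPositions(pssm, promoters[[id]], id = id, ...)$hits
  })
  do.call(rbind, out)
}

#' Aggregate positional hits into prevalence windows
#'
#' For each motif, x_i counts the promoters with a significant hit at
#' anchored coordinate i (at most one per promoter and coordinate). Every
#' distinct significant coordinate seeds a candidate window spanning
#' +/- \code{radius} nt; the window mass is X_j = sum of x_i over the span
#' and its prevalence is percent_j = 100 * X_j / sum_i x_i. The maximal
#' window is selected per motif, ties breaking toward the smallest
#' |center| and then the smallest center.
#'
#' @param hits data.frame with columns \code{motif}, \code{promoter_id},
#'   \code{position} (as from [collectHits()]).
#' @param radius window half-width in nt (default 4).
#' @return list with \code{windows} (all candidate windows: motif, center,
#'   start, end, X, percent) and \code{best} (one row per motif).
#' @export
aggregateWindows <- function(hits, radius = 4L) {
  empty <- data.frame(motif = character(0), center = integer(0),
                      start = integer(0), end = integer(0),
                      X = integer(0), percent = numeric(0))
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(windows = empty, best = empty))
  perMotif <- split(hits, hits$motif)
  winList <- lapply(names(perMotif), function(m) {
    h <- unique(perMotif[[m]][c("promoter_id", "position")])
    x <- table(h$position)
    coords <- as.integer(names(x))
    xs <- as.integer(x)
    total <- sum(xs)
    X <- vapply(coords, function(cc) sum(xs[abs(coords - cc) <= radius]),
                integer(1))
    data.frame(motif = m, center = coords,
               start = coords - as.integer(radius),
               end = coords + as.integer(radius),
               X = X, percent = 100 * X / total, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, winList)
  best <- do.call(rbind, lapply(split(windows, windows$motif), function(w) {
    w[order(-w$percent, abs(w$center), w$center), ][1L, ]
  }))
  rownames(best) <- NULL
  list(windows = windows, best = best)
}

#' Harmonize motif positions across the two datasets
#'
#' Dataset-B motifs survive if their maximal window prevalence exceeds
#' \code{prevalence} percent (strict inequality). A dataset-A motif
#' survives if its best-matching B motif survived and the two maximal
#' window centers are identical or within \code{radius} nt; its consensus
#' position is the midpoint of the two centers, rounded toward the A
#' center when fractional.
#'
#' @param bestA,bestB per-motif best windows (the \code{best} component of
#'   [aggregateWindows()]) for datasets A and B.
#' @param matches match table from [matchSets()] linking A motifs
#'   (\code{motif_a}) to B motifs (\code{motif_b}); only rows with
#'   \code{significant == TRUE} are used.
#' @param prevalence window prevalence threshold in percent (default 6.5).
#' @param radius cross-dataset position tolerance in nt (default 20).
#' @return data.frame: \code{motif}, \code{source}, \code{position},
#'   \code{percent}, \code{partner} (matched motif or NA).
#' @export
filterAndHarmonize <- function(bestA, bestB, matches,
                               prevalence = 6.5, radius = 20L) {
  keptB <- bestB[bestB$percent > prevalence, , drop = FALSE]
  outB <- if (nrow(keptB)) {
    data.frame(motif = keptB$motif, source = "datasetB",
               position = keptB$center, percent = keptB$percent,
               partner = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  outA <- NULL
  if (!is.null(matches) && nrow(matches)) {
    sig <- matches[matches$significant, , drop = FALSE]
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      ma <- sig$motif_a[i]
      mb <- sig$motif_b[i]
      ra <- bestA[bestA$motif == ma, , drop = FALSE]
      rb <- keptB[keptB$motif == mb, , drop = FALSE]
      if (nrow(ra) == 0L || nrow(rb) == 0L) return(NULL)
      cA <- ra$center[1L]
      cB <- rb$center[1L]
      if (abs(cA - cB) > radius) return(NULL)
      mid <- (cA + cB) / 2
      cons <- if (mid == floor(mid)) as.integer(mid)
              else if (cA > mid) as.integer(ceiling(mid))
              else as.integer(floor(mid))
      data.frame(motif = ma, source = "datasetA", position = cons,
                 percent = ra$percent[1L], partner = mb,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) outA <- do.call(rbind, rows)
  }
  out <- rbind(outA, outB)
  if (is.null(out))
    out <- data.frame(motif = character(0), source = character(0),
                      position = integer(0), percent = numeric(0),
                      partner = character(0))
  rownames(out) <- NULL
  out
}

#' Decide whether to insert or remove a motif in the target promoter
#'
#' Compares the motif's best score among its significant positions in the
#' target promoter (score_target) with the best across-promoter mean score
#' at its significant positions in the source promoters (score_reference;
#' the mean at each position is over the promoters significant there, then
#' the maximum over positions is taken). A motif from over-expressed
#' promoters is inserted when score_target < score_reference (its site in
#' the target is weaker than in its native promoters, direction
#' \code{"maximize"}); a motif from under-expressed promoters is removed
#' when score_target > score_reference (direction \code{"minimize"}).
#' Both inequalities are strict, so equality yields no action.
#'
#' @param pssm a [PSSM-class].
#' @param target target promoter sequence (single string).
#' @param targetPositions anchored coordinates of the motif's candidate
#'   (significant) positions in the target; must be non-empty.
#' @param sourceHits data.frame of the motif's significant hits across
#'   source promoters (columns \code{position}, \code{score}).
#' @param direction \code{"maximize"} (over-motif) or \code{"minimize"}
#'   (under-motif).
#' @return list of class \code{"InsertionPlan"}: motif, direction,
#'   target_position (argmax-score candidate), score_target,
#'   score_reference, decision.
#' @export
decideInsertion <- function(pssm, target, targetPositions, sourceHits,
                            direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  .stopIfNot(length(targetPositions) > 0,
             "no candidate positions in the target promoter")
  .stopIfNot(nrow(sourceHits) > 0,
             "motif '%s' has no significant source positions", motifName(pssm))
  prof <- slidingScores(pssm, target, id = "target")
  idx <- match(targetPositions, prof$position)
  .stopIfNot(!anyNA(idx), "candidate position outside the target's scanned range")
  tScores <- prof$score[idx]
  b <- which.max(tScores)
  scoreTarget <- tScores[b]
  posMeans <- tapply(sourceHits$score, sourceHits$position, mean)
  scoreReference <- max(posMeans)
  # strict inequalities; scores within numerical noise count as equal
  eps <- 1e-9
  decision <- if (direction == "maximize") scoreTarget < scoreReference - eps
              else scoreTarget > scoreReference + eps
  structure(list(motif = pssm, direction = direction,
                 target_position = as.integer(targetPositions[b]),
                 score_target = scoreTarget,
                 score_reference = as.numeric(scoreReference),
                 decision = decision),
            class = "InsertionPlan")
}

#' @export
print.InsertionPlan <- function(x, ...) {
  cat(sprintf(
    "InsertionPlan %s (%s): position %d, target %.3f vs reference %.3f -> %s\n",
    motifName(x$motif), x$direction, x$target_position,
    x$score_target, x$score_reference,
    if (x$decision) "act" else "no action"))
  invisible(x)
}
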