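# PSSM similarity with uniform edge padding, maximized over all relative
# alignments, plus row-permutation significance and cross-dataset best-match
# pairing.

#' Column-wise PSSM similarity score
#'
#' For two stochastic columns f1 and f2:
#' Observed = sum_j -(f1_j - f2_j)^2 and
#' Expected = sum_j sum_k -(f1_j - f2_k)^2 / 4 (all cross pairs of bases),
#' and the score is (Expected - Observed) / Expected. Identical columns
#' give 1 (Observed = 0); when both columns are exactly uniform both terms
#' vanish and the score is defined as 1 by continuity with the
#' identical-column limit. The score never exceeds 1.
#'
#' @param col1,col2 numeric 4-vectors summing to 1.
#' @return similarity score (dimensionless, <= 1).
#' @examples
#' columnScore(c(1, 0, 0, 0), c(0, 1, 0, 0))  # -1/3
#' @export
columnScore <- function(col1, col2) {
  .stopIfNot(length(col1) == 4L && length(col2) == 4L,
             "columns must be 4-vectors")
  .stopIfNot(abs(sum(col1) - 1) <= 1e-6 && abs(sum(col2) - 1) <= 1e-6,
             "columns must each sum to 1")
  obs <- -sum((col1 - col2)^2)
  expd <- -sum(outer(col1, col2, function(a, b) (a - b)^2)) / 4
  if (expd == 0) return(1)
  (expd - obs) / expd
}

# vectorized column scores for two aligned 4 x n matrices
.columnScores <- function(A, B) {
  obs <- -colSums((A - B)^2)
  # sum_jk (a_j - b_k)^2 = 4*sum(a^2) + 4*sum(b^2) - 2*(sum a)(sum b)
  expd <- -(4 * colSums(A^2) + 4 * colSums(B^2) - 2) / 4
  ifelse(expd == 0, 1, (expd - obs) / expd)
}

#' Alignment-maximized similarity between two PSSMs
#'
#' Every relative offset with at least one overlapping column is evaluated
#' (L1 + L2 - 1 configurations). For each configuration both matrices are
#' padded symmetrically with uniform columns (probability
#' \code{padding} = 0.25 per base) out to the union span, the column score
#' is averaged over the union span, and the reported similarity is the
#' maximum over configurations (ties keep the smallest offset).
#'
#' @param p1,p2 [PSSM-class] objects.
#' @param padding per-base probability of the padding columns.
#' @return list with \code{similarity}, \code{offset} (start of p2 relative
#'   to p1, 0 = aligned starts) and \code{span} (union span length).
#' @export
similarityScore <- function(p1, p2, padding = 0.25) {
  f1 <- freqMatrix(p1)
  f2 <- freqMatrix(p2)
  L1 <- ncol(f1)
  L2 <- ncol(f2)
  best <- -Inf
  bestOff <- NA_integer_
  bestSpan <- NA_integer_
  for (d in (1L - L2):(L1 - 1L)) {
    start <- min(1L, 1L + d)
    end <- max(L1, d + L2)
    span <- end - start + 1L
    A <- matrix(padding, 4L, span)
    B <- matrix(padding, 4L, span)
    A[, (1L - start + 1L):(L1 - start + 1L)] <- f1
    B[, (1L + d - start + 1L):(d + L2 - start + 1L)] <- f2
    sc <- mean(.columnScores(A, B))
    if (sc > best + 1e-12) {
      best <- sc
      bestOff <- d
      bestSpan <- span
    }
  }
  list(similarity = best, offset = bestOff, span = bestSpan,
       nConfigs = L1 + L2 - 1L)
}

#' Best-match pairing of two motif sets with permutation significance
#'
#' For each motif in \code{setA} the highest-similarity motif in
#' \code{setB} is selected. Significance of each best match is assessed by
#' permuting the nucleotide rows of the matched B motif \code{nPerm} times
#' and recomputing the similarity: p = fraction of permuted similarities
#' at least as large as the real one (ties count against significance).
#'
#' @param setA,setB lists of [PSSM-class].
#' @param nPerm number of row permutations (default 100).
#' @param alpha significance level for the \code{significant} flag.
#' @param padding per-base padding probability.
#' @param seed optional RNG seed for reproducible permutations.
#' @return data.frame: \code{motif_a}, \code{motif_b}, \code{similarity},
#'   \code{offset}, \code{p}, \code{significant}.
#' @export
matchSets <- function(setA, setB, nPerm = 100L, alpha = 0.05,
                      padding = 0.25, seed = NULL) {
  .stopIfNot(length(setA) > 0 && length(setB) > 0,
             "both motif sets must be non-empty")
  .withSeed(seed, {
    rows <- lapply(seq_along(setA), function(i) {
      a <- setA[[i]]
      sims <- vapply(setB, function(b) similarityScore(a, b, padding)$similarity,
                     numeric(1))
      j <- which.max(sims)
      bestMatch <- similarityScore(a, setB[[j]], padding)
      nulls <- vapply(seq_len(nPerm), function(k) {
        similarityScore(a, permutePssmRows(setB[[j]]), padding)$similarity
      }, numeric(1))
      p <- empiricalPvalue(bestMatch$similarity, nulls)
      data.frame(motif_a = motifName(a), motif_b = motifName(setB[[j]]),
                 index_b = j, similarity = bestMatch$similarity,
                 offset = bestMatch$offset, p = p,
                 significant = p <= alpha, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
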