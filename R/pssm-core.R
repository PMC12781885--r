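#' @importFrom stringi stri_sub stri_detect_regex stri_detect_fixed
NULL

PSSM_EPS <- 1e-3

# log2-odds lookup matrix against a uniform background with pseudocount.
.logOdds <- function(pssm) log2((pssm@freq + PSSM_EPS) / (0.25 + PSSM_EPS))

#' Score a single window under a PSSM
#'
#' The score is the log2-odds of the window under the motif against a
#' uniform background, with a pseudocount of 1e-3 added to both numerator
#' and background: sum_i log2((f[base_i, i] + 1e-3) / (0.25 + 1e-3)).
#' A uniform motif therefore scores 0 everywhere, and any monotone
#' transform of this choice would leave all rank-based downstream steps
#' unchanged.
#'
#' @param pssm a [PSSM-class].
#' @param window string of length \code{motifLength(pssm)} over A/C/G/T.
#' @return score in bits.
#' @examples
#' m <- pssm(matrix(c(1, 0, 0, 0), 4), name = "a")
#' scoreWindow(m, "A")  # ~ 1.995
#' @export
scoreWindow <- function(pssm, window) {
  L <- motifLength(pssm)
  .stopIfNot(nchar(window) == L,
             "window length %d does not match motif length %d",
             nchar(window), L)
  si <- .seqToInt(window, "window")
  lo <- .logOdds(pssm)
  sum(lo[cbind(si, seq_len(L))])
}

# fast path: score all windows of an integer-encoded sequence
.slideInt <- function(lo, si) {
  L <- ncol(lo)
  n <- length(si) - L + 1L
  sc <- numeric(n)
  for (o in seq_len(L)) sc <- sc + lo[cbind(si[o:(n + o - 1L)], o)]
  sc
}

#' Sliding-window PSSM scores along a promoter
#'
#' Scores every window start on the forward strand (the design target is a
#' promoter in fixed orientation; no reverse-complement scan).
#'
#' @param pssm a [PSSM-class].
#' @param promoter promoter sequence (single string over A/C/G/T).
#' @param id promoter identifier used in the result and error messages.
#' @return data.frame with columns \code{index} (1-based window start),
#'   \code{position} (start-codon-anchored coordinate of the window's first
#'   base) and \code{score} (bits); one row per valid start,
#'   \code{nchar(promoter) - motifLength(pssm) + 1} rows in total.
#' @export
slidingScores <- function(pssm, promoter, id = "promoter") {
  L <- motifLength(pssm)
  len <- nchar(promoter)
  .stopIfNot(len >= L, "promoter '%s' (%d nt) is shorter than the motif (%d nt)",
             id, len, L)
  si <- .seqToInt(promoter, id)
  sc <- .slideInt(.logOdds(pssm), si)
  idx <- seq_along(sc)
  data.frame(index = idx, position = anchorCoord(idx, len), score = sc)
}

#' Shuffle a promoter sequence
#'
#' Uniform mononucleotide permutation: the output is a random permutation
#' of the input bases, so base composition (hence GC content) is preserved
#' exactly.
#'
#' @param promoter sequence string.
#' @return shuffled sequence string.
#' @export
shuffleSequence <- function(promoter) {
  .intToSeq(sample(.seqToInt(promoter)))
}

#' Randomly permute the nucleotide rows of a PSSM
#'
#' Reorders the four rows (A, C, G, T) by a random permutation; columns
#' still sum to 1, so the result is a valid PSSM with the same per-column
#' information content but scrambled base identity. This is the null used
#' for motif-similarity significance.
#'
#' @param pssm a [PSSM-class].
#' @return a [PSSM-class] with permuted rows.
#' @export
permutePssmRows <- function(pssm) {
  f <- pssm@freq[sample(4L), , drop = FALSE]
  rownames(f) <- DNA_BASES
  pssm(f, name = pssm@name, source = pssm@source, direction = pssm@direction)
}

#' Empirical permutation p-value
#'
#' p = (number of random statistics >= the real statistic) / N. Ties count
#' toward the null (inclusive comparison), so a score equalled by 5 of 100
#' permutations gets p = 0.05 and is still called at alpha = 0.05.
#'
#' @param real observed statistic.
#' @param randoms vector of null statistics.
#' @return p-value in \[0, 1\].
#' @export
empiricalPvalue <- function(real, randoms) {
  .stopIfNot(length(randoms) > 0, "empirical p-value needs a non-empty null")
  mean(randoms >= real)
}

#' Build a PSSM from aligned sites
#'
#' Column frequencies are (count + pseudocount) / (n + 4 * pseudocount).
#'
#' @param sites character vector of equal-length fragments.
#' @param pseudocount per-cell pseudocount (default 0.5).
#' @param name,source,direction passed to [pssm()].
#' @return a [PSSM-class].
#' @export
buildPSSM <- function(sites, pseudocount = 0.5, name = "motif",
                      source = "external", direction = "neutral") {
  .stopIfNot(length(sites) >= 1L, "need at least one site")
  lens <- nchar(sites)
  .stopIfNot(length(unique(lens)) == 1L,
             "sites have ragged lengths (%s)", paste(unique(lens), collapse = ","))
  L <- lens[1L]
  n <- length(sites)
  counts <- matrix(0, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (s in sites) {
    si <- .seqToInt(s, "site")
    ij <- cbind(si, seq_len(L))
    counts[ij] <- counts[ij] + 1
  }
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  pssm(freq, name = name, source = source, direction = direction)
}

#' Generate a random PSSM (testing / null-model helper)
#'
#' Columns are drawn from a symmetric Dirichlet; small \code{concentration}
#' gives sharp (informative) columns.
#'
#' @param L motif length.
#' @param concentration Dirichlet concentration parameter.
#' @param name motif name.
#' @return a [PSSM-class].
#' @export
randomPSSM <- function(L, concentration = 0.5, name = "random") {
  g <- matrix(rgamma(4L * L, shape = concentration), 4L, L)
  f <- sweep(g, 2L, colSums(g), "/")
  rownames(f) <- DNA_BASES
  pssm(f, name = name)
}
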