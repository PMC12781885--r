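#' @importFrom data.table data.table rbindlist setkey .N :=
#' @importFrom stats phyper
NULL

# unique k-mers of one sequence (presence/absence per sequence feeds the
# enrichment test, not occurrence counts)
.kmersOf <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  unique(stri_sub(seq, seq_len(n), length = k))
}

# per-kmer presence counts over a set of sequences
.presenceCounts <- function(seqs, k) {
  dt <- data.table(kmer = unlist(lapply(seqs, .kmersOf, k = k),
                                 use.names = FALSE))
  if (nrow(dt) == 0L) return(dt[, .(kmer = character(0), n = integer(0))])
  dt[, list(n = .N), by = "kmer"]
}

.hamming <- function(a, b) {
  sum(stri_sub(a, seq_len(nchar(a)), length = 1L) !=
      stri_sub(b, seq_len(nchar(b)), length = 1L))
}

# a seed is absorbed by an already-emitted motif if it lies within Hamming
# distance 1 of any equal-length window of that motif's consensus
.absorbedBy <- function(seed, consensi) {
  k <- nchar(seed)
  for (cs in consensi) {
    n <- nchar(cs) - k + 1L
    if (n < 1L) {
      if (.hamming(stri_sub(seed, 1L, length = nchar(cs)), cs) <= 1L) return(TRUE)
      next
    }
    wins <- stri_sub(cs, seq_len(n), length = k)
    for (w in wins) if (.hamming(seed, w) <= 1L) return(TRUE)
  }
  FALSE
}

#' Differential k-mer motif discovery
#'
#' DREME-style discovery of motifs enriched in a target promoter set
#' relative to a reference set. Candidate seeds are all k-mers
#' (k in \code{kRange}) present in the target; each is tested for
#' per-sequence presence enrichment with a one-sided hypergeometric test
#' and Bonferroni correction over the tested k-mer universe. Significant
#' seeds, in order of increasing p, nucleate motifs: each target sequence
#' contributes its best-scoring window under the seed's matrix, the matrix
#' is rebuilt from those sites (two refinement passes), and nearby seeds
#' (within Hamming distance 1 of the emitted consensus) are absorbed.
#' When the reference set contains every target sequence (the
#' "target vs all" configurations) the reference itself is the
#' hypergeometric universe; otherwise the union of both sets is.
#'
#' The procedure is deterministic and invariant to the order of input
#' sequences.
#'
#' @param target,reference character vectors of promoter sequences.
#' @param kRange seed lengths to scan (default 6:10).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @param maxMotifs maximum motifs returned (default 50).
#' @param direction direction tag inherited by the discovered motifs.
#' @param source dataset tag for the discovered motifs.
#' @param minCount minimum target presence for a seed to be tested.
#' @return list with class \code{"DiscoveryResult"}: \code{motifs} (list of
#'   [PSSM-class]), \code{table} (data.frame motif/consensus/k/p_adjusted/
#'   direction), \code{configuration}.
#' @export
discoverMotifs <- function(target, reference, kRange = 6:10, alpha = 0.05,
                           maxMotifs = 50L, direction = "neutral",
                           source = "external", minCount = 3L) {
  .stopIfNot(length(target) > 0 && length(reference) > 0,
             "target and reference sets must be non-empty")
  .checkAlphabet(stats::setNames(target, seq_along(target)))
  .checkAlphabet(stats::setNames(reference, seq_along(reference)))
  .stopIfNot(max(kRange) <= min(nchar(c(target, reference))),
             "k range (max %d) exceeds the shortest sequence", max(kRange))

  inRef <- all(target %in% reference)
  universe <- if (inRef) reference else c(target, reference)
  nT <- length(target)
  nU <- length(universe)

  cand <- list()
  mTested <- 0L
  for (k in kRange) {
    tc <- .presenceCounts(target, k)
    uc <- if (inRef) .presenceCounts(reference, k) else {
      rc <- .presenceCounts(reference, k)
      merged <- merge(tc, rc, by = "kmer", all = TRUE)
      data.table::setnafill(merged, fill = 0L, cols = c("n.x", "n.y"))
      data.table(kmer = merged$kmer, n = merged$n.x + merged$n.y)
    }
    mTested <- mTested + nrow(uc)
    setkey(uc, kmer)
    tc <- tc[tc$n >= minCount, ]
    if (nrow(tc) == 0L) next
    K <- uc[tc$kmer, ]$n
    p <- phyper(tc$n - 1L, K, nU - K, nT, lower.tail = FALSE)
    cand[[length(cand) + 1L]] <-
      data.table(kmer = tc$kmer, k = k, x = tc$n, K = K, p = p)
  }
  if (length(cand) == 0L) {
    return(structure(list(motifs = list(),
                          table = data.frame(motif = character(0),
                                             consensus = character(0),
                                             k = integer(0),
                                             p_adjusted = numeric(0),
                                             direction = character(0)),
                          configuration = "custom"),
                     class = "DiscoveryResult"))
  }
  cand <- rbindlist(cand)
  cand[, "p_adj" := pmin(1, p * mTested)]
  cand <- cand[cand$p_adj <= alpha, ]
  cand <- cand[order(cand$p, cand$kmer), ]

  motifs <- list()
  rows <- list()
  consensi <- character(0)
  i <- 1L
  while (i <= nrow(cand) && length(motifs) < maxMotifs) {
    seed <- cand$kmer[i]
    if (!.absorbedBy(seed, consensi)) {
      m <- .refineSeed(seed, target, source = source, direction = direction)
      motifs[[length(motifs) + 1L]] <- m
      consensi <- c(consensi, motifConsensus(m), seed)
      rows[[length(rows) + 1L]] <-
        data.frame(motif = motifName(m), consensus = motifConsensus(m),
                   k = cand$k[i], p_adjusted = cand$p_adj[i],
                   direction = direction, stringsAsFactors = FALSE)
    }
    i <- i + 1L
  }
  structure(list(motifs = motifs,
                 table = if (length(rows)) do.call(rbind, rows) else
                   data.frame(motif = character(0), consensus = character(0),
                              k = integer(0), p_adjusted = numeric(0),
                              direction = character(0)),
                 configuration = "custom"),
            class = "DiscoveryResult")
}

# seed -> PSSM: start from the seed's near-one-hot matrix, then twice take
# each target sequence's best-scoring window and rebuild the matrix
.refineSeed <- function(seed, target, source, direction, iters = 2L) {
  m <- buildPSSM(seed, pseudocount = 0.4, name = seed,
                 source = source, direction = direction)
  tInts <- lapply(seq_along(target), function(j) .seqToInt(target[j], j))
  for (it in seq_len(iters)) {
    lo <- .logOdds(m)
    sites <- character(0)
    for (j in seq_along(tInts)) {
      sc <- .slideInt(lo, tInts[[j]])
      b <- which.max(sc)
      if (sc[b] > 0)
        sites <- c(sites, stri_sub(target[j], b, length = nchar(seed)))
    }
    if (length(sites) < 2L) break
    m <- buildPSSM(sites, pseudocount = 0.5, name = seed,
                   source = source, direction = direction)
  }
  m
}

#' @export
print.DiscoveryResult <- function(x, ...) {
  cat(sprintf("DiscoveryResult '%s': %d motif(s)\n",
              x$configuration, length(x$motifs)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Run the four discovery configurations
#'
#' Discovery is run with (1) over-expressed promoters vs all, (2) over vs
#' under, (3) under vs all, (4) under vs over, yielding four
#' \code{DiscoveryResult}s tagged over, over, under, under.
#'
#' @param over,under,all character vectors of promoter sequences;
#'   \code{over} and \code{under} must be disjoint subsets of \code{all}.
#' @param source dataset tag for discovered motifs.
#' @param ... passed to [discoverMotifs()].
#' @return list of four \code{DiscoveryResult}s named
#'   \code{over_vs_all}, \code{over_vs_under}, \code{under_vs_all},
#'   \code{under_vs_over}.
#' @export
runFourConfigurations <- function(over, under, all, source = "external", ...) {
  .stopIfNot(length(intersect(names(over), names(under))) == 0L &&
               !any(over %in% under),
             "over and under sets must be disjoint")
  cfgs <- list(
    over_vs_all   = list(t = over,  r = all,   d = "over"),
    over_vs_under = list(t = over,  r = under, d = "over"),
    under_vs_all  = list(t = under, r = all,   d = "under"),
    under_vs_over = list(t = under, r = over,  d = "under"))
  out <- lapply(names(cfgs), function(nm) {
    cf <- cfgs[[nm]]
    res <- discoverMotifs(cf$t, cf$r, direction = cf$d, source = source, ...)
    res$configuration <- nm
    if (nrow(res$table)) res$table$configuration <- nm
    res
  })
  names(out) <- names(cfgs)
  out
}
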