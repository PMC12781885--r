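# Transcription-factor motif scans with shuffle nulls and the extreme-group
# rank comparison.

#' Scan a promoter with a transcription-factor PSSM catalog
#'
#' For each TF matrix the maximum sliding-window score and its position
#' are extracted; significance is the empirical p-value of that maximum
#' against the maxima over \code{nPerm} composition-preserving shuffles of
#' the promoter (the same shuffled promoters are reused across the
#' catalog). Motifs longer than the promoter are skipped with a warning.
#'
#' @param promoter promoter sequence string.
#' @param tfPssms list of [PSSM-class] (TF catalog).
#' @param nPerm number of shuffles (default 100).
#' @param seed RNG seed.
#' @return data.frame: \code{tf}, \code{max_score}, \code{position}
#'   (anchored coordinate of the maximum), \code{p}.
#' @export
scanTf <- function(promoter, tfPssms, nPerm = 100L, seed = NULL) {
  len <- nchar(promoter)
  keep <- vapply(tfPssms, function(m) motifLength(m) <= len, logical(1))
  if (any(!keep))
    warning(sum(!keep), " motif(s) longer than the promoter skipped")
  tfPssms <- tfPssms[keep]
  si <- .seqToInt(promoter, "promoter")
  .withSeed(seed, {
    shuffles <- lapply(seq_len(nPerm), function(i) sample(si))
    rows <- lapply(tfPssms, function(m) {
      lo <- .logOdds(m)
      sc <- .slideInt(lo, si)
      b <- which.max(sc)
      nullMax <- vapply(shuffles, function(s) max(.slideInt(lo, s)),
                        numeric(1))
      data.frame(tf = motifName(m), max_score = sc[b],
                 position = anchorCoord(b, len),
                 p = empiricalPvalue(sc[b], nullMax),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Rank-sum comparison of the extreme response groups
#'
#' Splits variants into the top and bottom \code{fraction} by the ranking
#' values (e.g. maximum net luminescence) and compares the per-variant
#' scores (e.g. a TF's maximum PSSM score) between the two groups with a
#' two-sided Wilcoxon rank-sum test. Invariant to monotone transforms of
#' the ranking values.
#'
#' @param scores named numeric vector of per-variant scores.
#' @param ranking named numeric vector used to rank variants (same ids).
#' @param fraction extreme-group fraction (default 0.20).
#' @return list: \code{p}, \code{top}, \code{bottom} (id vectors),
#'   \code{flag} (\code{"all_tied"} when every score is identical,
#'   otherwise \code{"ok"}).
#' @export
compareExtremeGroups <- function(scores, ranking, fraction = 0.20) {
  ids <- intersect(names(scores), names(ranking))
  .stopIfNot(length(ids) > 0, "scores and ranking share no ids")
  g <- selectGroups(ranking[ids], fraction = fraction)
  .stopIfNot(length(g$over) >= 5L, "need at least 5 variants per group")
  top <- scores[g$over]
  bottom <- scores[g$under]
  if (length(unique(c(top, bottom))) == 1L)
    return(list(p = 1, top = g$over, bottom = g$under, flag = "all_tied"))
  p <- suppressWarnings(
    wilcox.test(top, bottom, alternative = "two.sided", correct = TRUE)$p.value)
  list(p = p, top = g$over, bottom = g$under, flag = "ok")
}
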