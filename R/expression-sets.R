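#' Bin-weighted mean fluorescence of a flow-seq variant
#'
#' The per-variant expression estimate from sorted-bin sequencing counts:
#' F = sum_i b_i n_i / sum_i n_i, where b_i is the mean fluorescence of
#' bin i and n_i the variant's read count in that bin. Invariant to
#' rescaling all counts of the variant by a constant.
#'
#' @param counts numeric vector of per-bin counts (length = number of bins).
#' @param binMeans strictly increasing vector of per-bin mean fluorescence.
#' @return weighted mean fluorescence, or \code{NA_real_} with a warning if
#'   all counts are zero (record excluded downstream).
#' @export
weightedFluorescence <- function(counts, binMeans) {
  .stopIfNot(length(counts) == length(binMeans),
             "counts (%d) and bin means (%d) differ in length",
             length(counts), length(binMeans))
  tot <- sum(counts)
  if (tot == 0) {
    warning("all-zero bin counts: weighted fluorescence undefined")
    return(NA_real_)
  }
  sum(binMeans * counts) / tot
}

#' Bin-weighted fluorescence for a whole flow-seq table
#'
#' @param df bin-count data.frame as from [readBinCounts()].
#' @param binMeans per-bin mean fluorescence vector.
#' @param condition optional condition filter (e.g. \code{"DNT"}).
#' @return data.frame \code{variant_id}, \code{condition}, \code{F};
#'   all-zero records are dropped with a warning.
#' @export
flowSeqFluorescence <- function(df, binMeans, condition = NULL) {
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  cols <- paste0("n_", seq_along(binMeans))
  cnt <- as.matrix(df[cols])
  tot <- rowSums(cnt)
  keep <- tot > 0
  if (any(!keep))
    warning(sum(!keep), " record(s) with all-zero counts excluded")
  data.frame(variant_id = df$variant_id[keep],
             condition = df$condition[keep],
             F = as.numeric(cnt[keep, , drop = FALSE] %*% binMeans) / tot[keep],
             stringsAsFactors = FALSE)
}

#' Select over- and under-expressed extreme groups
#'
#' Takes the top and bottom \code{ceiling(fraction * n)} ids by score.
#' Boundary ties break lexicographically by id, so the grouping is
#' reproducible; the two groups are guaranteed disjoint.
#'
#' @param values named numeric vector (id -> ranking score).
#' @param fraction extreme-group fraction (default 0.10).
#' @return list with character vectors \code{over} and \code{under}.
#' @export
selectGroups <- function(values, fraction = 0.10) {
  .stopIfNot(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  n <- length(values)
  k <- as.integer(ceiling(fraction * n))
  .stopIfNot(n >= 2L * k,
             "%d records cannot hold two disjoint groups of %d", n, k)
  ids <- names(values)
  .stopIfNot(!is.null(ids) && !anyDuplicated(ids), "values must have unique names")
  over <- ids[order(-values, ids)][seq_len(k)]
  rest <- setdiff(ids, over)
  vrest <- values[rest]
  under <- rest[order(vrest, rest)][seq_len(k)]
  list(over = over, under = under)
}
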