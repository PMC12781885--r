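# Greedy refinement of a motif site and constrained variant-library
# construction. "Insertion" is substitution-in-place: the promoter keeps
# its length, as the library is synthesized as fixed-length replacements
# between the KpnI and SwaI sites.

KPNI_SITE <- "GGTACC"
SWAI_SITE <- "ATTTAAAT"

#' Immutable coordinates of a control promoter
#'
#' Marks the restriction-site spans that must stay intact in every variant
#' (all occurrences of KpnI GGTACC and SwaI ATTTAAAT in the control), plus
#' any user-supplied anchored coordinates.
#'
#' @param control control promoter sequence (single string).
#' @param extra additional anchored coordinates to protect.
#' @param sites restriction-site strings to locate (default KpnI, SwaI).
#' @return sorted integer vector of anchored immutable coordinates.
#' @export
constraintMask <- function(control, extra = integer(0),
                           sites = c(KPNI_SITE, SWAI_SITE)) {
  len <- nchar(control)
  coords <- integer(0)
  for (s in sites) {
    hits <- gregexpr(s, control, fixed = TRUE)[[1]]
    if (hits[1L] != -1L)
      for (h in hits) coords <- c(coords, seq(h, h + nchar(s) - 1L))
  }
  coords <- anchorCoord(coords, len)
  out <- sort(unique(c(as.integer(coords), as.integer(extra))))
  .stopIfNot(all(out >= -len & out <= -1L) || length(out) == 0L,
             "mask coordinates outside the promoter span")
  out
}

#' Greedy hill-climb refinement of a motif site
#'
#' Starting from the promoter subsequence of motif length at the plan's
#' target position, each iteration enumerates every single-nucleotide
#' substitution at unmasked positions (excluding the position changed in
#' the immediately preceding iteration, which is frozen for one
#' iteration), applies the substitution with the largest strict score
#' improvement (increase for direction \code{"maximize"}, decrease for
#' \code{"minimize"}), and stops when no substitution improves. Ties break
#' toward the smaller coordinate, then the alphabetically first base. The
#' score trace is strictly monotone and the iteration count is bounded by
#' the motif length (each accepted move sets one column to its optimum).
#'
#' @param promoter promoter sequence containing the site.
#' @param plan an \code{InsertionPlan} (from [decideInsertion()]) whose
#'   \code{decision} is TRUE.
#' @param mask anchored immutable coordinates (default none).
#' @return list: \code{fragment} (refined site), \code{initial} (original
#'   site), \code{edits} (data.frame coordinate/ref/new), \code{trace}
#'   (data.frame iteration/position/base/score), \code{score}.
#' @export
refineMotifSequence <- function(promoter, plan, mask = integer(0)) {
  .stopIfNot(isTRUE(plan$decision), "plan decision is FALSE; nothing to refine")
  m <- plan$motif
  L <- motifLength(m)
  len <- nchar(promoter)
  start <- unanchorCoord(plan$target_position, len)
  .stopIfNot(start >= 1L && start + L - 1L <= len,
             "target position %d puts the site outside the promoter",
             plan$target_position)
  lo <- .logOdds(m)
  frag <- .seqToInt(stri_sub(promoter, start, length = L), "site")
  coords <- anchorCoord(start:(start + L - 1L), len)
  mutable <- which(!(coords %in% mask))
  if (length(mutable) == 0L)
    stop("no mutable positions: the whole site is masked")
  sgn <- if (plan$direction == "maximize") 1 else -1
  score <- sum(lo[cbind(frag, seq_len(L))])
  trace <- list()
  frozen <- 0L
  it <- 0L
  repeat {
    bestGain <- 0
    bestP <- 0L
    bestB <- 0L
    for (p in mutable) {
      if (p == frozen) next
      for (b in 1:4) {
        if (b == frag[p]) next
        gain <- sgn * unname(lo[b, p] - lo[frag[p], p])
        # strict ">" keeps the first optimum met, i.e. the smallest
        # coordinate and then the alphabetically first base on ties
        if (gain > bestGain + 1e-12) {
          bestGain <- gain
          bestP <- p
          bestB <- b
        }
      }
    }
    if (bestP == 0L) break
    it <- it + 1L
    frag[bestP] <- bestB
    score <- score + sgn * bestGain
    trace[[it]] <- data.frame(iteration = it,
                              position = coords[bestP],
                              base = DNA_BASES[bestB],
                              score = score)
    frozen <- bestP
  }
  refined <- .intToSeq(frag)
  orig <- stri_sub(promoter, start, length = L)
  diffs <- which(stri_sub(refined, seq_len(L), length = 1L) !=
                 stri_sub(orig, seq_len(L), length = 1L))
  edits <- data.frame(
    coordinate = coords[diffs],
    ref = stri_sub(orig, diffs, length = 1L),
    new = stri_sub(refined, diffs, length = 1L),
    stringsAsFactors = FALSE)
  list(fragment = refined, initial = orig, edits = edits,
       trace = if (it > 0) do.call(rbind, trace) else
         data.frame(iteration = integer(0), position = integer(0),
                    base = character(0), score = numeric(0)),
       score = score)
}

.applyEdits <- function(control, edits) {
  len <- nchar(control)
  v <- stri_sub(control, seq_len(len), length = 1L)
  idx <- unanchorCoord(edits$coordinate, len)
  stopifnot(all(v[idx] == edits$ref))
  v[idx] <- edits$new
  paste(v, collapse = "")
}

#' Build the constrained variant library
#'
#' Each accepted plan is refined at its target site and contributes one
#' single-plan variant; every (A, B) plan pair whose site spans do not
#' overlap contributes a combined variant (Cartesian product with the
#' non-overlap condition). Plans whose edits touch a masked coordinate are
#' rejected with the offending coordinates named; plans whose refinement
#' produces no change yield no variant. Variants are deduplicated by
#' sequence.
#'
#' @param control control promoter sequence.
#' @param plansA,plansB lists of \code{InsertionPlan}s from datasets A and
#'   B (either may be empty).
#' @param mask anchored immutable coordinates (default: restriction sites
#'   of the control, via [constraintMask()]).
#' @return list of class \code{"VariantLibrary"}: \code{variants} (list of
#'   per-variant lists with id, sequence, edits, plans, tags),
#'   \code{table} (summary data.frame), \code{rejected} (data.frame of
#'   rejected plans and reasons), \code{control}.
#' @export
buildVariantLibrary <- function(control, plansA, plansB,
                                mask = constraintMask(control)) {
  refineSet <- function(plans, prefix) {
    out <- list()
    rejected <- list()
    for (i in seq_along(plans)) {
      pl <- plans[[i]]
      r <- refineMotifSequence(control, pl, mask = integer(0))
      bad <- intersect(r$edits$coordinate, mask)
      if (length(bad)) {
        rejected[[length(rejected) + 1L]] <- data.frame(
          plan = sprintf("%s%d", prefix, i), motif = motifName(pl$motif),
          reason = paste0("edits hit masked coordinate(s) ",
                          paste(bad, collapse = ",")),
          stringsAsFactors = FALSE)
        next
      }
      if (nrow(r$edits) == 0L) next
      L <- motifLength(pl$motif)
      out[[length(out) + 1L]] <- list(
        id = sprintf("%s%d", prefix, i), plan = pl, refined = r,
        span = c(pl$target_position, pl$target_position + L - 1L))
    }
    list(kept = out, rejected = rejected)
  }
  ra <- refineSet(plansA, "A")
  rb <- refineSet(plansB, "B")
  rejected <- do.call(rbind, c(ra$rejected, rb$rejected))

  variants <- list()
  addVariant <- function(id, edits, planIds, tags) {
    seqv <- .applyEdits(control, edits)
    variants[[length(variants) + 1L]] <<- list(
      id = id, sequence = seqv, edits = edits, plans_used = planIds,
      dataset_tags = tags)
  }
  for (v in ra$kept) addVariant(v$id, v$refined$edits, v$id, "datasetA")
  for (v in rb$kept) addVariant(v$id, v$refined$edits, v$id, "datasetB")
  for (va in ra$kept) {
    for (vb in rb$kept) {
      overlap <- va$span[1L] <= vb$span[2L] && vb$span[1L] <= va$span[2L]
      if (overlap) next
      edits <- rbind(va$refined$edits, vb$refined$edits)
      edits <- edits[order(edits$coordinate), ]
      addVariant(paste(va$id, vb$id, sep = "_"), edits,
                 c(va$id, vb$id), c("datasetA", "datasetB"))
    }
  }
  seqsSeen <- character(0)
  keep <- logical(length(variants))
  for (i in seq_along(variants)) {
    s <- variants[[i]]$sequence
    keep[i] <- !(s %in% seqsSeen)
    seqsSeen <- c(seqsSeen, s)
  }
  variants <- variants[keep]
  tab <- if (length(variants)) {
    data.frame(
      variant_id = vapply(variants, `[[`, character(1), "id"),
      n_edits = vapply(variants, function(v) nrow(v$edits), integer(1)),
      plans = vapply(variants, function(v)
        paste(v$plans_used, collapse = "+"), character(1)),
      stringsAsFactors = FALSE)
  } else data.frame(variant_id = character(0), n_edits = integer(0),
                    plans = character(0))
  structure(list(variants = variants, table = tab,
                 rejected = if (is.null(rejected))
                   data.frame(plan = character(0), motif = character(0),
                              reason = character(0)) else rejected,
                 control = control),
            class = "VariantLibrary")
}

#' @export
print.VariantLibrary <- function(x, ...) {
  cat(sprintf("VariantLibrary: %d variant(s), %d rejected plan(s)\n",
              length(x$variants), nrow(x$rejected)))
  invisible(x)
}

#' Sequences of a variant library
#'
#' @param lib a \code{VariantLibrary}.
#' @param includeControl prepend the control sequence (id "control").
#' @return named character vector of variant sequences.
#' @export
librarySequences <- function(lib, includeControl = TRUE) {
  seqs <- vapply(lib$variants, `[[`, character(1), "sequence")
  names(seqs) <- vapply(lib$variants, `[[`, character(1), "id")
  if (includeControl) seqs <- c(control = lib$control, seqs)
  seqs
}

#' Write a variant library as FASTA plus a JSON edit manifest
#'
#' @param lib a \code{VariantLibrary}.
#' @param fastaPath,jsonPath output paths.
#' @return invisibly, the two paths.
#' @export
writeVariantLibrary <- function(lib, fastaPath, jsonPath) {
  writeSequences(librarySequences(lib, includeControl = FALSE), fastaPath)
  manifest <- lapply(lib$variants, function(v) {
    list(id = v$id, plans = v$plans_used, tags = v$dataset_tags,
         edits = v$edits)
  })
  jsonlite::write_json(manifest, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(fastaPath, jsonPath))
}
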