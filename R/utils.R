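# Coordinate conventions: internally sequences are 1-based strings; the
# user-facing coordinate system is anchored to the start codon, so the base
# immediately upstream of the ATG is -1 and a 400-nt promoter spans -400..-1.

#' Convert 1-based indices to start-codon-anchored coordinates
#'
#' @param index 1-based position(s) within the promoter.
#' @param len promoter length.
#' @return signed anchored coordinate(s); the last base maps to -1.
#' @export
anchorCoord <- function(index, len) as.integer(index - len - 1L)

#' Convert start-codon-anchored coordinates to 1-based indices
#'
#' @param coord anchored coordinate(s) (negative upstream of the ATG).
#' @param len promoter length.
#' @return 1-based index/indices.
#' @export
unanchorCoord <- function(coord, len) as.integer(coord + len + 1L)

# integer encoding A=1 C=2 G=3 T=4; errors identify the offending record
.seqToInt <- function(seq, id = "sequence") {
  v <- match(stri_sub(seq, seq_len(nchar(seq)), length = 1L), DNA_BASES)
  if (anyNA(v))
    stop(sprintf("record '%s' contains non-ACGT character(s)", id))
  v
}

.intToSeq <- function(v) paste(DNA_BASES[v], collapse = "")

.checkAlphabet <- function(seqs) {
  bad <- stri_detect_regex(seqs, "[^ACGT]")
  if (any(bad))
    stop("record '", names(seqs)[bad][1L],
         "' contains characters outside A/C/G/T")
  invisible(TRUE)
}

# local RNG scope: run code under a given seed without disturbing the
# caller's RNG stream
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  code
}

.stopIfNot <- function(cond, ...) if (!cond) stop(sprintf(...), call. = FALSE)
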