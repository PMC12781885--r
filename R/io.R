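#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read promoter sequences from FASTA
#'
#' Sequences are upper-cased on read; any character outside A/C/G/T is a
#' parse error naming the offending record, and duplicate ids are
#' rejected. With \code{anchorRule = "end"} the start codon is taken to
#' follow the promoter immediately, so a 400-nt promoter spans anchored
#' coordinates -400..-1.
#'
#' @param path FASTA file.
#' @param anchorRule currently \code{"end"} (start codon immediately after
#'   the promoter).
#' @return named character vector of sequences, with attribute
#'   \code{anchorRule}.
#' @export
readSequences <- function(path, anchorRule = "end") {
  anchorRule <- match.arg(anchorRule, "end")
  ss <- readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1L])
  .checkAlphabet(seqs)
  attr(seqs, "anchorRule") <- anchorRule
  seqs
}

#' Write promoter sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSequences <- function(seqs, path) {
  ss <- DNAStringSet(unclass(seqs)[seq_along(seqs)])
  names(ss) <- names(seqs)
  writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the MEME minimal motif text format (a \code{MOTIF} line followed
#' by a \code{letter-probability matrix} block of L rows x 4 columns in
#' A, C, G, T order). Columns off stochasticity by more than 1e-6 are
#' renormalized with a warning; negative entries or rows with other than 4
#' fields are parse errors.
#'
#' @param path motif file.
#' @param source,direction tags applied to every motif read.
#' @return list of [PSSM-class].
#' @export
readMotifs <- function(path, source = "external", direction = "neutral") {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF records in ", path)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    hdr <- starts[i] + which(grepl("^letter-probability matrix",
                                   lines[(starts[i] + 1):length(lines)]))[1]
    if (is.na(hdr)) stop("motif '", name, "': missing letter-probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])
    w <- suppressWarnings(as.integer(w))
    rows <- list()
    j <- hdr + 1
    while (j <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[j])) {
      fields <- as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      if (length(fields) != 4L)
        stop("motif '", name, "': matrix row with ", length(fields),
             " fields (expected 4)")
      if (any(fields < 0))
        stop("motif '", name, "': negative probability entry")
      rows[[length(rows) + 1L]] <- fields
      j <- j + 1
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", name, "': w=", w, " but ", length(rows), " matrix rows")
    f <- t(do.call(rbind, rows))
    rownames(f) <- DNA_BASES
    cs <- colSums(f)
    if (any(cs <= 0)) stop("motif '", name, "': zero-sum column")
    if (any(abs(cs - 1) > 1e-6)) {
      warning("motif '", name, "': columns renormalized to sum 1")
      f <- sweep(f, 2L, cs, "/")
    }
    out[[i]] <- pssm(f, name = name, source = source, direction = direction)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs list of [PSSM-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", motifName(m)), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       motifLength(m)), con)
    f <- freqMatrix(m)
    for (i in seq_len(ncol(f)))
      writeLines(paste(sprintf("%.8f", f[, i]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Load a RunConfig from a YAML file
#'
#' Unset keys take the package defaults (see [RunConfig-class]); unknown
#' keys are an error rather than being silently ignored. The fully
#' resolved configuration is echoed via \code{message()}.
#'
#' @param path YAML file of key-value pairs (may be empty).
#' @param verbose echo the resolved configuration (default TRUE).
#' @return a [RunConfig-class].
#' @export
loadConfig <- function(path, verbose = TRUE) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  cfg <- do.call(runConfig, vals)
  if (verbose) {
    for (s in slotNames("RunConfig"))
      message(sprintf("config %-20s = %s", s, format(slot(cfg, s))))
  }
  cfg
}

# --- TSV tables -------------------------------------------------------------

.readTsv <- function(path, required) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-condition expression table
#'
#' @param path TSV with header \code{gene_id}, \code{expr_dnt},
#'   \code{expr_ctrl}.
#' @return data.frame with a recomputed \code{delta} column
#'   (\code{expr_dnt - expr_ctrl}).
#' @export
readExpressionTable <- function(path) {
  df <- .readTsv(path, c("gene_id", "expr_dnt", "expr_ctrl"))
  df$delta <- df$expr_dnt - df$expr_ctrl
  df
}

#' @rdname readExpressionTable
#' @param df expression data.frame.
#' @export
writeExpressionTable <- function(df, path) {
  .writeTsv(df[c("gene_id", "expr_dnt", "expr_ctrl")], path)
}

#' Read flow-seq bin counts
#'
#' @param path TSV with header \code{variant_id}, \code{condition} and
#'   \code{n_1}..\code{n_16}.
#' @param bins number of fluorescence bins (default 16).
#' @return data.frame; counts are checked to be non-negative integers.
#' @export
readBinCounts <- function(path, bins = 16L) {
  cols <- paste0("n_", seq_len(bins))
  df <- .readTsv(path, c("variant_id", "condition", cols))
  cnt <- as.matrix(df[cols])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("bin counts must be non-negative integers")
  df
}

#' @rdname readBinCounts
#' @param df bin-count data.frame.
#' @export
writeBinCounts <- function(df, path) .writeTsv(df, path)

#' Read per-bin mean fluorescence values
#'
#' @param path TSV with header \code{bin}, \code{mean_fluorescence};
#'   values must be strictly increasing (logarithmic bins).
#' @return numeric vector of bin means.
#' @export
readBinMeans <- function(path) {
  df <- .readTsv(path, c("bin", "mean_fluorescence"))
  b <- df$mean_fluorescence[order(df$bin)]
  if (any(diff(b) <= 0)) stop("bin means must be strictly increasing")
  b
}

#' Read a promoter-strength energy matrix
#'
#' @param path TSV: first column \code{base} (A, C, G, T), remaining 41
#'   columns named by anchored position -41..-1; values in kBT.
#' @return 4 x 41 numeric matrix with rownames A,C,G,T.
#' @export
readEnergyMatrix <- function(path) {
  df <- .readTsv(path, "base")
  m <- as.matrix(df[setdiff(names(df), "base")])
  rownames(m) <- df$base
  m <- m[DNA_BASES, , drop = FALSE]
  if (ncol(m) != 41L) stop("energy matrix must have 41 position columns")
  if (!all(is.finite(m))) stop("energy matrix entries must be finite")
  m
}

#' Read a luminescence time-course table
#'
#' @param path TSV with header \code{variant_id}, \code{replicate},
#'   \code{time}, \code{lum_dnt}, \code{lum_ctrl}.
#' @return data.frame.
#' @export
readLuminescence <- function(path) {
  .readTsv(path, c("variant_id", "replicate", "time", "lum_dnt", "lum_ctrl"))
}

#' @rdname readLuminescence
#' @param df luminescence data.frame.
#' @export
writeLuminescence <- function(df, path) .writeTsv(df, path)
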