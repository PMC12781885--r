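#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Position-specific scoring matrix
#'
#' A \code{PSSM} holds per-column nucleotide probabilities for an ungapped
#' sequence motif: a 4 x L column-stochastic matrix with rows A, C, G, T.
#' The \code{source} tag records which dataset the motif was discovered in
#' and \code{direction} whether it came from over- or under-expressed
#' promoters (which decides whether a design step tries to strengthen or
#' weaken its site).
#'
#' @slot name character motif identifier.
#' @slot freq 4 x L numeric matrix; each column sums to 1.
#' @slot source one of \code{"datasetA"}, \code{"datasetB"}, \code{"external"}.
#' @slot direction one of \code{"over"}, \code{"under"}, \code{"neutral"}.
#'
#' @exportClass PSSM
setClass("PSSM",
  representation(
    name = "character",
    freq = "matrix",
    source = "character",
    direction = "character"
  ),
  prototype(name = "motif", source = "external", direction = "neutral")
)

setValidity("PSSM", function(object) {
  f <- object@freq
  msg <- character(0)
  if (!is.numeric(f) || nrow(f) != 4L)
    msg <- c(msg, "freq must be a numeric 4 x L matrix")
  else {
    if (ncol(f) < 1L) msg <- c(msg, "motif length must be >= 1")
    if (!identical(rownames(f), DNA_BASES))
      msg <- c(msg, "freq rows must be named A, C, G, T")
    if (any(f < 0)) msg <- c(msg, "freq entries must be non-negative")
    if (any(abs(colSums(f) - 1) > 1e-6))
      msg <- c(msg, "each freq column must sum to 1 (tolerance 1e-6)")
  }
  if (!object@source %in% c("datasetA", "datasetB", "external"))
    msg <- c(msg, "source must be datasetA, datasetB or external")
  if (!object@direction %in% c("over", "under", "neutral"))
    msg <- c(msg, "direction must be over, under or neutral")
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM
#'
#' @param freq 4 x L numeric matrix of column probabilities (rows A,C,G,T;
#'   row names are set if absent). Columns are renormalized only by
#'   [buildPSSM()] / [readMotifs()]; here they must already be stochastic.
#' @param name motif identifier.
#' @param source dataset tag (\code{"datasetA"}, \code{"datasetB"},
#'   \code{"external"}).
#' @param direction \code{"over"}, \code{"under"} or \code{"neutral"}.
#' @return a [PSSM-class] object.
#' @examples
#' m <- pssm(matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), 4), name = "ex")
#' motifLength(m)
#' @export
pssm <- function(freq, name = "motif", source = "external",
                 direction = "neutral") {
  freq <- as.matrix(freq)
  if (nrow(freq) == 4L && is.null(rownames(freq))) rownames(freq) <- DNA_BASES
  new("PSSM", name = name, freq = freq, source = source, direction = direction)
}

#' @describeIn pssm motif name accessor
#' @param x a \code{PSSM}
#' @export
motifName <- function(x) x@name

#' @describeIn pssm probability matrix accessor
#' @export
freqMatrix <- function(x) x@freq

#' @describeIn pssm number of columns (motif width)
#' @export
motifLength <- function(x) ncol(x@freq)

#' @describeIn pssm dataset-of-origin tag
#' @export
motifSource <- function(x) x@source

#' @describeIn pssm over/under/neutral direction tag
#' @export
motifDirection <- function(x) x@direction

#' @describeIn pssm per-column most probable base, as a string (ties break
#'   alphabetically)
#' @export
motifConsensus <- function(x) {
  paste(DNA_BASES[apply(x@freq, 2L, which.max)], collapse = "")
}

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM '%s' (%s, %s), length %d, consensus %s\n",
              object@name, object@source, object@direction,
              motifLength(object), motifConsensus(object)))
  print(round(object@freq, 3))
})

#' Variant-by-feature table
#'
#' Holds the numeric feature matrix for a set of promoter variants together
#' with per-feature metadata (the category each feature belongs to:
#' folding, mutation, chimera, motif_pssm, strength, composition or rbs).
#'
#' @slot values numeric matrix, variants in rows, features in columns.
#' @slot meta data.frame with columns \code{feature} and \code{category},
#'   one row per column of \code{values}, in the same order.
#'
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", meta = "data.frame"))

FEATURE_CATEGORIES <- c("folding", "mutation", "chimera", "motif_pssm",
                        "strength", "composition", "rbs")

setValidity("FeatureTable", function(object) {
  msg <- character(0)
  v <- object@values
  m <- object@meta
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (anyNA(v)) msg <- c(msg, "feature values must not contain NA")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "feature names must be present and unique")
  if (!all(c("feature", "category") %in% names(m)))
    msg <- c(msg, "meta needs 'feature' and 'category' columns")
  else {
    if (!identical(m$feature, colnames(v)))
      msg <- c(msg, "meta$feature must match colnames(values) in order")
    if (!all(m$category %in% FEATURE_CATEGORIES))
      msg <- c(msg, paste("categories must be one of:",
                          paste(FEATURE_CATEGORIES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix (variants x features) with dimnames.
#' @param category character vector of per-feature categories, recycled if
#'   length 1.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(values, category) {
  values <- as.matrix(values)
  if (length(category) == 1L) category <- rep(category, ncol(values))
  meta <- data.frame(feature = colnames(values), category = category,
                     stringsAsFactors = FALSE)
  new("FeatureTable", values = values, meta = meta)
}

#' @describeIn featureTable numeric matrix accessor
#' @param x a \code{FeatureTable}
#' @export
featureValues <- function(x) x@values

#' @describeIn featureTable per-feature metadata accessor
#' @export
featureMeta <- function(x) x@meta

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d variants x %d features\n",
              nrow(object@values), ncol(object@values)))
  print(table(object@meta$category))
})

#' Combine feature tables column-wise
#'
#' @param ... \code{FeatureTable} objects over the same variants.
#' @return a single [FeatureTable-class].
#' @export
cbindFeatureTables <- function(...) {
  tabs <- list(...)
  vals <- do.call(cbind, lapply(tabs, featureValues))
  meta <- do.call(rbind, lapply(tabs, featureMeta))
  new("FeatureTable", values = vals, meta = meta)
}

#' Pipeline run configuration
#'
#' Bundles the tunable parameters shared across pipeline stages, with the
#' standard defaults: 100 permutations, significance level 0.05, uniform
#' padding probability 0.25 for motif alignment, positional windows of
#' +/- 4 nt, positional prevalence threshold 6.5%, cross-dataset position
#' radius 20 nt, folding windows of 40 nt at step 1, extreme-group fraction
#' 0.10, folding-feature Spearman redundancy cutoff 0.99 and 10
#' cross-validation repeats.
#'
#' @slot seed integer RNG seed.
#' @slot nPermutations permutation count for empirical p-values.
#' @slot alpha significance level.
#' @slot paddingValue uniform probability used to pad motif edges.
#' @slot windowRadius positional window half-width (nt).
#' @slot prevalenceThreshold window prevalence threshold (percent).
#' @slot crossDatasetRadius cross-dataset position tolerance (nt).
#' @slot foldWindow folding window size (nt).
#' @slot foldStep folding window step (nt).
#' @slot groupFraction extreme-group fraction.
#' @slot spearmanCutoff folding-feature redundancy cutoff.
#' @slot cvRepeats cross-validation repeats.
#'
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    seed = "integer", nPermutations = "integer", alpha = "numeric",
    paddingValue = "numeric", windowRadius = "integer",
    prevalenceThreshold = "numeric", crossDatasetRadius = "integer",
    foldWindow = "integer", foldStep = "integer", groupFraction = "numeric",
    spearmanCutoff = "numeric", cvRepeats = "integer"
  ),
  prototype(
    seed = 1L, nPermutations = 100L, alpha = 0.05, paddingValue = 0.25,
    windowRadius = 4L, prevalenceThreshold = 6.5, crossDatasetRadius = 20L,
    foldWindow = 40L, foldStep = 1L, groupFraction = 0.10,
    spearmanCutoff = 0.99, cvRepeats = 10L
  )
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  chkFrac <- function(v, nm) {
    if (!(v > 0 && v < 1)) sprintf("%s must lie in (0, 1)", nm) else character(0)
  }
  chkPos <- function(v, nm) {
    if (!(is.finite(v) && v > 0)) sprintf("%s must be positive", nm) else character(0)
  }
  msg <- c(msg,
    chkFrac(object@alpha, "alpha"),
    chkFrac(object@paddingValue, "paddingValue"),
    chkFrac(object@groupFraction, "groupFraction"),
    chkFrac(object@spearmanCutoff, "spearmanCutoff"),
    chkPos(object@nPermutations, "nPermutations"),
    chkPos(object@windowRadius, "windowRadius"),
    chkPos(object@crossDatasetRadius, "crossDatasetRadius"),
    chkPos(object@foldWindow, "foldWindow"),
    chkPos(object@foldStep, "foldStep"),
    chkPos(object@cvRepeats, "cvRepeats"))
  if (!(object@prevalenceThreshold >= 0 && object@prevalenceThreshold <= 100))
    msg <- c(msg, "prevalenceThreshold must be a percent in [0, 100]")
  if (length(msg)) msg else TRUE
}
)

#' Build a RunConfig from named values
#'
#' @param ... named overrides of the defaults (see [RunConfig-class]).
#' @return a validated [RunConfig-class].
#' @examples
#' cfg <- runConfig(alpha = 0.01)
#' cfg@nPermutations
#' @export
runConfig <- function(...) {
  args <- list(...)
  slots <- slotNames("RunConfig")
  unknown <- setdiff(names(args), slots)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  intSlots <- c("seed", "nPermutations", "windowRadius", "crossDatasetRadius",
                "foldWindow", "foldStep", "cvRepeats")
  for (nm in intersect(names(args), intSlots)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("RunConfig"), args))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  for (s in slotNames("RunConfig"))
    cat(sprintf("  %-20s %s\n", s, format(slot(object, s))))
})
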