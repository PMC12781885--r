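# shared test helpers: small deterministic sequence/motif constructors

randSeq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# promoter with a given site substituted in at a 1-based index
withSite <- function(seq, site, at) {
  paste0(substr(seq, 1, at - 1), site,
         substr(seq, at + nchar(site), nchar(seq)))
}

uniformPSSM <- function(L, name = "uniform") {
  pssm(matrix(0.25, 4, L), name = name)
}

# sharp PSSM whose consensus is `cons` (probability `p` on the consensus base)
sharpPSSM <- function(cons, p = 0.91, name = cons) {
  L <- nchar(cons)
  f <- matrix((1 - p) / 3, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  f[cbind(idx, seq_len(L))] <- p
  pssm(f, name = name)
}

# exhaustive maximum/minimum of a PSSM's window score over all 4^L windows
bruteForceScoreRange <- function(m) {
  L <- motifLength(m)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  lo <- log2((freqMatrix(m) + 1e-3) / (0.25 + 1e-3))
  sc <- numeric(nrow(grid))
  for (o in seq_len(L)) sc <- sc + lo[cbind(grid[, o], o)]
  c(min = min(sc), max = max(sc))
}

viennaAvailable <- function() Sys.which("RNAfold") != ""
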