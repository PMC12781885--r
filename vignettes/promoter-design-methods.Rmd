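---
title: "Methods: promoter design and response modeling in PromoterForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter design and response modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PromoterForge)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the parameters that matter, the
numerical conventions, and the design choices made where the procedure
was genuinely open. The companion README shows a worked example; the
test suite and `scripts/acceptance.R` compute every empirical claim made
here.

## Coordinates and data model

Promoters are plain A/C/G/T strings anchored to the start codon: the
base immediately upstream of the ATG has coordinate -1, so a 400-nt
promoter spans -400..-1. Internally everything is 1-based;
`anchorCoord()`/`unanchorCoord()` convert. Motifs are `PSSM` S4 objects
(4 x L column-stochastic matrices, rows A, C, G, T) carrying a dataset
tag and a direction tag (`over`/`under`) that decides whether the design
step will try to strengthen or weaken the motif's site.

## PSSM scoring

No single canonical "PSSM score" exists, so the package fixes one and
uses it everywhere: the log2-odds of the window against a uniform
background with a pseudocount of 1e-3,

score(w) = sum_i log2((f[w_i, i] + 0.001) / (0.25 + 0.001)).

A uniform matrix scores exactly 0 at every window. Every downstream use
of scores is rank-based (empirical p-values, maxima, greedy
improvement), so any monotone transform of this choice would produce the
same pipeline decisions; the specific form only fixes the reported
numbers. Scanning is forward-strand only: the design target is a
promoter in a fixed orientation, and its mutagenized variants inherit
that orientation.

## Empirical p-values

All significance in the motif pipeline is permutation-based with
`nPermutations = 100` by default:

* **Positions**: the promoter is shuffled by uniform mononucleotide
  permutation (base composition and GC content preserved exactly), and
  each position's observed score is compared with the null scores *at
  the same position* across shuffles. The alternative — comparing with
  the promoter-wide null maximum — answers a different question ("is
  there a site anywhere?") and is used only in the TF scan, where the
  maximum is precisely the statistic of interest.
* **Motif matches**: the partner matrix's four nucleotide rows are
  permuted; a row permutation preserves per-column information content
  while destroying base identity.

The p-value convention is inclusive: p = (# null >= observed) / N, so
ties count against significance and p = 0.05 with 5 of 100 exceedances
is still called at alpha = 0.05. With 100 permutations, p-values are
multiples of 0.01 and the probability that a null statistic lands at
p <= 0.05 is 6/101 = 0.0594, not 0.0500 — the price of the inclusive
convention at finite N. The calibration test therefore pools on the
order of 200 null tests, where the 95% binomial band around 0.05 is
wide enough to contain this intrinsic discreteness; at much larger test
counts the band would shrink below it and the check would reject its
own estimator.

## Motif discovery

The discovery step needs only to be a reasonable differential-enrichment
algorithm; the package uses a deterministic DREME-style scheme:

1. every k-mer (k = 6..10) present in the target set is a candidate
   seed; presence is per-sequence (a sequence counts once however many
   occurrences it has);
2. seeds are tested by a one-sided hypergeometric test of presence in
   the target versus the universe — the reference set itself when it
   contains the target (the "target vs all" configurations, detected by
   sequence membership), otherwise the union of both sets — with
   Bonferroni correction over all tested k-mers;
3. significant seeds, in order of increasing p, nucleate motifs: each
   target sequence contributes its best-scoring window, the matrix is
   rebuilt from those sites (pseudocount 0.5), twice; seeds within
   Hamming distance 1 of an emitted consensus are absorbed.

The procedure consumes no randomness and is invariant to the order of
input sequences. Note that with a planted site, the emitted consensus
may be a sub-k-mer or a junction-shifted variant of the planted word
(flanking bases are co-enriched); the similarity metric, which
maximizes over alignment offsets, handles this downstream. Discovered
motif counts are data-dependent outputs, not targets.

## Motif similarity (cross-dataset matching)

For aligned columns the score is `(Expected - Observed)/Expected` with
`Observed = -sum_j (f1_j - f2_j)^2` and the expectation computed over
all 16 cross pairs of bases, `Expected = -sum_{j,k} (f1_j - f2_k)^2/4`.
Without the cross index the two terms would be identical and every
score would collapse to zero, so the cross-pair form is the only
non-degenerate reading and the one implemented. Identical columns give
exactly 1; two exactly uniform columns give 0/0 and are defined as 1 by
continuity with the identical-column limit; a one-hot mismatch gives
-1/3. Matrices of different lengths are compared at every relative
offset with at least one overlapping column (L1 + L2 - 1
configurations), both matrices padded symmetrically with uniform 0.25
columns to the union span, the column scores averaged over the union
span, and the maximum taken. The score never exceeds 1, and the metric
is exactly symmetric.

## Site selection and the insertion decision

Significant positions are pooled across the relevant promoters; x_i
counts promoters with a hit at coordinate i (once per promoter and
coordinate). Each observed significant coordinate seeds a candidate
window of +/-4 nt; the window mass is X_j = sum of x_i over the span
and its prevalence percent_j = 100 X_j / sum_i x_i (the denominator is
the total hit mass, so overlapping windows can sum above 100 while each
stays in [0, 100]). The maximal window is selected, ties broken toward
the smallest |center| then the smallest center — candidate windows are
centered only on observed coordinates, keeping the search discrete and
reproducible.

Dataset-B motifs must exceed 6.5% prevalence (strict); dataset-A motifs
survive if their best-matching B motif survived and the two window
centers agree within +/-20 nt, with the consensus position taken as the
midpoint rounded toward the A center.

The decision to act compares the motif's best score among its
significant positions in the design target with the best across-promoter
mean score at its significant source positions (mean per position first,
maximum second). Insertion requires the target site to be strictly
weaker (for over-motifs) or stronger (for under-motifs) than that
reference; scores within 1e-9 are treated as equal and yield no action,
since strict inequalities on floating-point sums would otherwise flip
on last-ulp differences.

## Greedy refinement and library construction

Refinement hill-climbs over single-nucleotide substitutions at unmasked
positions, applying the largest strictly improving change, freezing the
just-changed position for exactly one iteration (the non-cumulative
reading of "without altering the position changed in the last
iteration"; cumulative freezing would also terminate but can stop short
of the optimum). Because column contributions are independent, each
accepted move sets a column to its per-column optimum, so the trace is
strictly monotone, the iteration count is bounded by the motif length,
and the unconstrained optimum equals the exhaustive 4^L maximum (or
minimum) — verified against brute force for L <= 6 in the tests. Ties
break toward the smaller coordinate and then the alphabetically first
base.

"Insertion" is substitution-in-place: the library is synthesized as
fixed-length promoter replacements between restriction sites, so
promoter length never changes. The default mask protects every KpnI
(`GGTACC`) and SwaI (`ATTTAAAT`) occurrence in the control. Plans are
refined first and rejected — with the offending coordinates named — if
any edit lands in the mask. The library holds one variant per accepted
plan plus one per non-overlapping (A, B) plan pair (site spans, not
just edited bases, must be disjoint), deduplicated by sequence.

## Feature extraction

* **Folding**: minimum free energy of every 40-nt window (step 1,
  window labelled by its first base), their mean, and the whole-variant
  MFE. Energies come from the ViennaRNA nearest-neighbor implementation
  (`RNAfold`), applied to the promoter sequence under RNA rules — the
  same convention as computing "DNA folding" with an RNA-folding
  routine, kept for comparability. Windows are deduplicated at
  |Spearman rho| > 0.99, keeping the left-most representative; constant
  windows are kept and flagged.
* **Mutations**: per-position indicator vs the control plus the total;
  indicators at adjacent coordinates (within 1 nt — the package's
  fixed reading of "similar positions") are averaged into profile
  features.
* **ChimeraARS**: mean over start positions of the longest substring
  also present in a reference set (no match contributes 0); checked
  against a quadratic brute force in the tests.
* **Motif scores**: per-motif maximum sliding score, for inserted,
  discovered and cataloged motifs (a 37-motif synthetic regulon-style
  catalog ships under `inst/extdata` for tests and examples).
* **Promoter strength**: a 4 x 41 energy matrix (kBT) over offsets
  -41..-1 from the TSS; contribution = matrix[base, offset], plus total
  and mean. The matrix is an input; a documented synthetic one ships
  for tests. Where the TSS of a variant is unknown, the packaged
  convention is tss = -1 (the 41 nt nearest the start codon).
* **Composition and RBS**: mono-/dinucleotide counts and frequencies,
  GC; and per-6-nt-window hybridization free energy against the
  anti-Shine-Dalgarno core (default `ACCUCCUUA`, configurable) from the
  nearest-neighbor duplex model (`RNAduplex`), forward strand only.

Extraction is a pure function of its inputs; identical sequences and
catalogs give bit-identical tables. The package does not try to hit any
particular total feature count — the inventory is defined by the
categories above and the input catalogs.

## Response modeling

Net luminescence delta(t) = induced - uninduced is linearly interpolated
onto a shared time grid; beyond the measured span the boundary value is
held constant (the least-assuming extrapolation). The four response
variables are the maximum, mean, maximal consecutive slope, and time of
first maximum of delta(t). K-means with a correlation metric (row
z-scoring makes Euclidean k-means equivalent, and leaves labels
invariant to per-profile affine rescaling) is evaluated over candidate
K by silhouette (on the 1 - r distance) and Davies-Bouldin; on
disagreement the silhouette choice wins and the disagreement is logged.

Three regression harnesses run over seed-deterministic repeated random
splits (default 10): linear regression with 60/20/20 splits and forward
selection maximizing the test-set Pearson correlation; an L1-penalized
linear model with 80/20 splits and the regularization path chosen by
internal cross-validation; and gradient-boosted trees with 60/20/20
splits, forward selection, and hyperparameters chosen once by a
budgeted random search (default 20 trials) scored on validation R² —
random search is the package's budgeted stand-in for sequential
model-based optimization at desk scale, and the found configuration is
shared across repeats to keep the harness tractable. Forward selection
accepts a feature only on strict improvement of the held-out objective,
so the selection path is monotone.

Classification splits variants into three balanced classes at the
tertiles of control-relative maximum net luminescence (the thresholds
are not dictated by the method beyond balance, so tertiles are the
canonical balanced choice; heavy ties make the split degenerate and
raise an error). An RBF-kernel SVM and boosted trees run over 80/20
splits with forward selection on held-out accuracy. The permutation
null refits the better classifier on 100 label permutations using the
features selected under the real labels — rerunning the full selection
per permutation would multiply the cost a hundredfold; reusing the
selected features makes the null, if anything, slightly harder to beat.

Importance analysis combines (1) cross-repeat selection frequency with
a top-10%-of-features cut, after merging folding windows within 10 nt
and motif features one substitution apart, (2) tree-gain ranking, and
(3) signed additive attributions (SHAP values); per-variant
attributions plus the baseline reproduce the model prediction exactly
in single precision, which bounds the achievable absolute agreement at
roughly 1e-7 times the prediction scale.

Per-variant significance is a Welch two-sample t-test of each variant's
replicate values against the control's. With two replicates per group
this test is fragile (df near 2) and is provided as the study-design
match, not a statistical endorsement. The false-discovery estimate
pools all values, reassigns them at random to the same variant/control
structure, and reports FDR = mean null significant count / observed
significant count.

EC200 — the dose at which the induced/uninduced ratio reaches 2 — is
found at the first crossing, interpolating log(ratio) linearly in
log10(dose) between the bracketing doses (the log-log form follows the
multiplicative character of both axes); an exact hit returns that dose,
a curve that never reaches 2 returns a "not reached" result, and
non-monotone curves use the first crossing with a warning.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed) and default to
the pipeline's study conditions: dataset A with 500 genes x 400-nt
promoters, a designated 10% over-expressed subset carrying one planted
8-mer (`TGACCTTA`, information content far above the discovery
threshold) at -120 with 10% per-site substitution noise and a
3-5 sigma expression shift; dataset B with 2000 variants of a 200-nt
base promoter mutated at 147 designated sites (1-3 substitutions per
variant), log-normal fluorescence with per-site effects, a 4x inducer
multiplier for motif carriers, and multinomial reads at depth 200 over
16 logarithmically spaced bins; luminescence as a logistic rise
(onset 2.5 h, reproducing a lagged sigmoidal signal) whose amplitude is
linear in designated true features, with two replicates. Background
composition is uniform by default; an AT-rich option exists because
motif-recovery difficulty depends on it.

Passing tests on these data establish that the algorithms recover what
was planted under the stated noise — they do not establish that real
promoter libraries satisfy the generative assumptions (independent
per-site effects, i.i.d. backgrounds, logistic kinetics, multinomial
sorting). Two behaviors seen on synthetic data are worth knowing about:
with a shared-backbone mutagenesis library, background matches of a
motif recur at identical coordinates in every variant, so positional
prevalence can favor backbone sites over the causal one (the
cross-dataset harmonization step exists precisely to discipline this);
and discovery may return a junction-shifted or truncated version of a
planted word, which the offset-maximizing similarity absorbs.

## Problem sizes and runtime conventions

The test suite runs the end-to-end recovery at 20 seeds of the full
study conditions (500 + 2000 sequences per seed) and keeps the model
harnesses at 120 variants x ~30 features with 10 repeats and a
10-trial hyperparameter budget — sizes chosen so the whole suite
completes in a few minutes on one core while leaving every statistical
check at its stated power. `scripts/acceptance.R` uses the same sizes.
The package's user-facing functions have no such limits.

## Interface choice

The package is used from R: the exported functions, this vignette and
`scripts/acceptance.R` are the interface. No shell entry point is
shipped — every pipeline stage is a documented function, which composes
better inside R analyses than a subcommand CLI would.

## Known limitations

Forward-strand scanning only; no gapped motifs or EM refinement; no
dinucleotide-preserving shuffles (the nulls preserve composition, not
adjacency); the discovery scheme is one reasonable instance of
differential enrichment, not a reimplementation of any specific tool;
Welch tests on duplicate measurements are underpowered by construction;
and the energy-matrix and TF catalogs shipped with the package are
synthetic stand-ins for licensed or unpublished resources, suitable for
tests and examples but not for biological inference.
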