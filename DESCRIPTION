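Package: PromoterForge
Title: Computational Design and Analysis of Stress-Responsive Promoter Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for engineering inducible bacterial promoters from
    expression data. Discovers condition-responsive sequence motifs from an
    endogenous promoter expression set and a flow-seq mutagenesis library,
    matches motifs across datasets with a padded position-specific scoring
    matrix (PSSM) similarity metric and permutation significance, selects
    insertion sites by positional prevalence, refines motif sequences by
    greedy hill climbing, and emits a constrained variant library. Includes
    sequence feature extraction (folding-energy windows, ChimeraARS,
    promoter strength, anti-Shine-Dalgarno hybridization), regression and
    classification harnesses with forward feature selection and permutation
    validation, transcription-factor motif scans, dose-response EC200
    estimation, and seeded synthetic-data generators with planted ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    stringi,
    data.table,
    jsonlite,
    yaml,
    glmnet,
    xgboost,
    e1071,
    cluster
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, MotifDiscovery, SequenceMatching, Regression, Classification
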