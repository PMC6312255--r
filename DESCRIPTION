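Package: radOmics
Title: Integrative Dose-Response Analysis of Cardiac Proteome and Transcriptome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for studying ionizing-radiation dose effects
    on protein and transcript expression in the presence of a confounded age
    covariate. Implements per-protein Box-Cox transformation and backward
    stepwise AIC regression to separate dose-only from age-only dependent
    features, Kruskal-Wallis screening with Storey q-values and Dunnett
    many-to-one post-hoc tests with non-monotone (U-shape / cap-shape)
    dose-response classification, a minimal negative-binomial Wald test for
    two-group transcript differential expression, and Fisher combined
    p-value integration of the proteome and transcriptome layers with a
    restrictive-intersection comparator, gene-set over-representation, and
    exploratory clustering. Ships a synthetic cohort generator that emulates
    the dose/age correlation structure of an occupationally exposed worker
    cohort, with ground-truth labels for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    mvtnorm,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    multcomp,
    DESeq2
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, DifferentialExpression, Regression,
    MultipleComparison, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'config.R'
    'deconvolution.R'
    'doseResponse.R'
    'enrichment.R'
    'explore.R'
    'integration.R'
    'io.R'
    'preprocess.R'
    'runAll.R'
    'simulate.R'
    'transcriptDE.R'
    'utils.R'
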