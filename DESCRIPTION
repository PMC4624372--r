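Package: SFPquant
Title: Quantification and Classification of Seminal Fluid Proteomes Under
    Sperm Competition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free quantitative proteomics workflow for studying
    plasticity of seminal fluid composition in response to sperm-competition
    cues. Implements Top3 peptide-to-protein quantification, median-log-ratio
    normalisation to all proteins or to a reference set of ejaculated
    proteins, replicated random-forest classification of samples with an
    out-of-bag permutation test, variable-importance feature selection,
    proximity-based multidimensional scaling and outlier scoring, per-protein
    t-tests with Benjamini-Hochberg q-values, ANOVA screening with fold
    changes, hierarchical-clustering preparation for heatmaps, and factorial
    and mixed-model analysis of sperm-production morphometrics. A synthetic
    data generator reproduces the statistical structure of a 2x2
    sperm-competition by mating-rate study so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
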