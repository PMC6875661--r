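Package: invadapt
Title: Niche Conservatism and Post-Introduction Adaptation in Invasive Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis chain for testing niche shift versus niche
    conservatism during biological invasions. Implements niche-overlap
    statistics (Schoener's D) with equivalency and similarity permutation
    tests on kernel-smoothed occurrence-density grids; ensemble species
    distribution modelling with surface-range-envelope pseudo-absences,
    TSS/ROC evaluation, permutation variable importance and map-agreement
    niche-change metrics (stability, expansion, unfilling); dual
    genotype-environment association scans (latent-factor mixed models and
    ancestry-conditioned partial redundancy analysis) with genomic
    inflation-factor calibration, Storey q-values and cross-method outlier
    intersection; generalized dissimilarity modelling of per-locus allelic
    turnover from pairwise Weir-Cockerham FST with monotone I-splines, a
    random-SNP reference null and a three-criterion candidate
    classification; and landmark-based wing morphometrics with generalized
    Procrustes alignment, shape ordination, type II ANOVA/MANOVA and
    environment-conditioned redundancy analysis. A synthetic-data module
    generates every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    mgcv,
    splines,
    glmnet,
    randomForest,
    xgboost,
    vegan,
    car,
    pROC,
    pracma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
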