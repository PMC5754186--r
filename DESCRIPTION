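Package: qrscan
Title: Quantile-Regression Genome-Wide Association Scans for Plant Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage genome-wide association analysis for quantitative
    traits measured in multi-environment plant trials. Stage one fits a
    REML mixed model (genotype, genotype-by-environment and block random
    effects) to produce adjusted phenotypes, entry-mean heritabilities and
    genetic correlations. Stage two scans SNP dosages one marker at a time,
    either by ordinary least squares or by check-loss quantile regression
    across a grid of quantiles, with principal-component covariates for
    population structure and Bonferroni genome-wide thresholds. The
    quantile-regression estimator is an exact vertex (simplex) solver for
    the check-loss linear program, with rank-score, Wald and bootstrap
    inference, and the Koenker-Machado pseudo-R1 goodness of fit. A
    Balding-Nichols genotype and multi-environment phenotype simulator
    reproduces the statistical structure the pipeline assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    lme4,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), quantreg, optparse, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'qrscan-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'io.R'
    'lmm.R'
    'pca.R'
    'pipeline.R'
    'preprocess.R'
    'qr.R'
    'scan.R'
    'simulate.R'
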