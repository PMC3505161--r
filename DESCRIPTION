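Package: countvar
Title: Variance Structure of mRNA-Seq Gene Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes technical, biological and experimental variance
    in gene-level sequencing counts. Per-gene log-link generalized linear
    models are fit under Poisson, over-dispersed Poisson and negative
    binomial variance functions with normalization offsets (total or
    upper-quartile count) and categorical blocking factors (flow cell,
    lane-pair, library batch). Dispersion can be estimated per gene by
    profile likelihood, globally by Cox-Reid adjusted profile likelihood,
    or per gene with empirical-Bayes shrinkage towards the global value.
    Diagnostics include Pearson goodness-of-fit QQ data against chi-square
    references, technical-replicate pair checks (pair Pearson statistics,
    MVA coordinates, rank correlation), the within-group mean-variance
    characterization with fitted variance laws, and a null-simulation
    calibration of the chi-square reference. A synthetic lane-count
    generator emulates a balanced two-group flow-cell design with
    technical-replicate lanes, a mid-study depth shift and Gamma-mixed
    biological variability, providing ground truth for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    MASS,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: RNASeq, Regression, DifferentialExpression, QualityControl
RoxygenNote: 7.3.3
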