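Package: BCDA
Title: Bias-Corrected Differential Abundance Analysis for Microbiome Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential absolute-abundance analysis of microbiome count
    tables under an offset-based log-linear model that corrects both
    sample-specific sampling fractions and taxon-specific sequencing
    efficiencies. Provides iterative bias estimation with an EM Gaussian
    mixture correction, structural-zero detection, prevalence filtering and a
    pseudo-count sensitivity filter, multigroup inference under mixed
    directional false discovery rate (mdFDR) control, order-restricted
    (pattern) analysis over ordered groups with a Williams-type statistic,
    a restricted maximum likelihood extension for repeated measures, a
    Poisson log-normal simulator, and an FDR/power evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    Matrix,
    jsonlite,
    optparse,
    SummarizedExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, DifferentialExpression, Metagenomics, Normalization,
    Sequencing, Software
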