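Package: twinvar
Title: Variance Decomposition of Antibody-Array Profiles in Longitudinal Twin Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to partition the phenotypic variance of antibody suspension
    bead array protein profiles measured on monozygotic and dizygotic twin
    pairs into familial, individual-environmental, common-visit,
    individual-visit and experimental components. Includes a synthetic twin
    cohort generator mirroring a longitudinal two-visit, duplicate-aliquot,
    multi-plate design; probabilistic quotient normalization; replicate
    concordance assessment via Spearman correlation; multivariate outlier
    screening on principal-component scores with a chi-squared rule; per-assay
    Box-Cox transformation by profile maximum likelihood; blockwise
    maximum-likelihood estimation of the twin linear mixed-effects model with
    plate fixed effects and optional plate-specific well-position drift; AIC
    model selection; and cohort-level summaries of the resulting variance
    proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    optparse
Config/testthat/edition: 3
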