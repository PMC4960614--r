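Package: pgstrend
Title: Polygenic Score Penetrance Trends Across Birth Cohorts
Version: 0.1.0
Authors@R:
    person("pgstrend", "maintainers", email = "maintainers@pgstrend.org",
           role = c("aut", "cre"))
Description: Tools to study how the association between a polygenic score
    (PGS) and its phenotype changes across birth cohorts. Builds additive
    polygenic scores from GWAS summary-statistic weights with
    strand-ambiguity filtering and allele-orientation matching,
    residualizes scores on genotype principal components to guard against
    population stratification, fits a PGS-by-birth-year interaction model
    with classical and household-clustered (Huber-White) covariance,
    corrects the interaction estimate for score measurement error by
    simulation-extrapolation (SIMEX), checks PGS variance stability across
    cohorts, and summarizes fits as binned means by score sign. A
    synthetic-cohort generator (Hardy-Weinberg genotypes with optional
    two-subpopulation structure, noisy published weights, spousal
    household clustering, wave-long phenotypes, and optional mortality
    selection) makes every stage testable without access-restricted
    survey genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    optparse,
    VariantAnnotation,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
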