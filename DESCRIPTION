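Package: pleiokit
Title: Genetic Correlations from SNP Data and Twin Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of genome-wide pleiotropy between paired quantitative
    traits from two independent designs: bivariate GREML (average-information
    REML against a genomic relationship matrix built from SNP dosages) for
    conventionally unrelated individuals, and a bivariate Cholesky ACE model
    fitted to monozygotic and dizygotic twin pairs by full-information maximum
    likelihood. Includes the surrounding pipeline: simulation of genotypes
    under the Balding-Nichols model, bivariate phenotypes with a known
    pleiotropic architecture and twin pairs from a biometric model; phenotype
    preprocessing (outlier exclusion, covariate residualization, van der
    Waerden quantile normalization, unit-weighted composites); GRM
    construction with relatedness pruning; LD pruning, ancestry principal
    components and Tracy-Widom axis selection; and a config-driven workflow
    that emits report tables for the genetic, shared- and non-shared
    environmental correlations with delta-method standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
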