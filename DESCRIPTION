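Package: gsemr
Title: Structural Equation Models of Genetic Variance in Unrelated Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate variance-component structural equation models in
    which latent additive-genetic factors are anchored by a genome-wide
    genetic relationship matrix (GRM) rather than twin correlations, fitted
    by full-information maximum likelihood in samples of nominally unrelated
    individuals. Provides GRM construction from SNP dosages with
    relatedness pruning and GCTA binary GRM input/output, phenotype
    preparation (covariate residualization and rank-based inverse normal
    transformation), Cholesky, independent-pathway and common-pathway AE
    factor models with arbitrary reduced loading patterns, delta-method
    standard errors for genetic variances and correlations, Wald and
    likelihood-ratio tests with AIC/BIC model comparison, stepwise model
    reduction, and a genotype-phenotype simulation harness for estimator
    accuracy studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
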