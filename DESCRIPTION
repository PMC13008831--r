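Package: boldqg
Title: Bayesian Quantitative Genetics of Boldness and Survival in Pedigreed
    Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate Bayesian animal models for repeated, right-censored
    behavioural assays and binary survival in pedigreed populations. Provides
    pedigree validation and additive-relationship algebra (A, its sparse
    inverse, inbreeding coefficients), a Gibbs sampler for linear mixed models
    with pedigree-linked random effects, unstructured age-specific covariance
    blocks, censored-Gaussian and probit threshold responses, a breeding-design
    simulator emulating a paternal half-sib three-generation study of guppy
    boldness (emergence-time assays censored at 300 s) with survival-linked
    attrition, and derived posterior statistics: heritability, maternal-effect
    and repeatability ratios, cross-age genetic correlations,
    genotype-by-sex/age contrasts, Holm-adjusted age contrasts, and
    boldness-survival associations on the liability scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
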