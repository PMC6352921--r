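Package: famvar
Title: Variance Components, Polygenic Scores and Genetic Correlation in
    Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes phenotypic variance in family-structured cohorts
    into SNP-genetic, residual pedigree-genetic and shared-environment
    (nuclear family, couple, full-sibling) components by restricted
    maximum likelihood, with likelihood-ratio and Wald tests, backward
    stepwise model selection, observed-to-liability-scale conversion and
    GREML power calculation.  Also provides clump-based polygenic risk
    scoring with mixed-model association, leave-one-chromosome-out
    mixed-model GWAS, LD score regression for SNP heritability and
    cross-trait genetic correlation, and a family-based simulator of
    pedigrees, Mendelian genotypes and multi-component phenotypes with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
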