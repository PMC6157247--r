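Package: phenimpute
Title: Pedigree-Aware Conditional Multivariate Normal Phenotype Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes missing quantitative phenotypes in family studies by
    conditional multivariate normal prediction, borrowing information from
    relatives through the pedigree relationship matrix and from a correlated
    second phenotype through a bivariate polygenic model fitted by maximum
    likelihood. Provides pedigree parsing and kinship computation, block-wise
    conditional-mean imputation, linear mixed model score tests for
    SNP-phenotype association with a pedigree random effect, a gene-dropping
    family-study simulator, and drivers evaluating type-I error, power and
    imputation accuracy of analyses on imputed versus incomplete data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, optparse, vcfR
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'utils.R'
    'pedigree.R'
    'covariance.R'
    'fit.R'
    'impute.R'
    'association.R'
    'io.R'
    'simulate.R'
    'evaluate.R'
    'cli.R'
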