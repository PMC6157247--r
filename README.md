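# phenimpute

Pedigree-aware imputation of missing quantitative phenotypes for
family-based association studies, with mixed-model score-test association
and a synthetic family-study simulator for evaluating the whole pipeline.

## What it does

Complete-case analysis throws away every sample with a missing phenotype
and with it association power. When a correlated second phenotype exists
and samples have phenotyped relatives, missing values can be reconstructed
instead. `phenimpute` models the stacked bivariate phenotype vector `Y`
(length `2n`) as multivariate normal with covariance

    Sigma = Sigma_A ⊗ phi + Sigma_E ⊗ I

where `phi` is the pedigree relationship matrix (twice the kinship matrix),
`Sigma_A` the 2×2 additive-genetic covariance of the two phenotypes, and
`Sigma_E` their environmental covariance. After estimating `Sigma_A`,
`Sigma_E` by maximum likelihood from the observed entries, missing values
are replaced by the conditional mean

    E(Y_m | Y_o) = mu_m + Sigma_mo Sigma_oo^{-1} (Y_o − mu_o)

and SNP association is tested on the completed data with a linear mixed
model carrying a `tau * phi + sigma2 * I` random-effect covariance (1-df
score test, additive coding).

The package covers the full workflow: PLINK `.fam`/PED pedigree parsing,
kinship computation (`computePhi`) or genotype-based relatedness
(`empiricalPhi`), bivariate variance-component fitting
(`fitBivariatePolygenic`), conditional-mean imputation (`imputePanel`,
`carryoverFill`, `imputeVisit3`), association (`fitNullModel`,
`scanGenotypes`), a gene-dropping simulator (`simulateStudy`), and
evaluation drivers (`runType1`, `runPower`, `runMSE`) that compare
analyses of incomplete versus imputed data. A command-line wrapper is
installed at `system.file("cli", "phenimpute.R", package = "phenimpute")`.

## Worked example

```r
library(phenimpute)

## a synthetic study: 170 nuclear families (680 samples), 4 log-scale
## visits, 17.2% of visit-3 values missing, 5 causal + 200 null SNPs
cfg   <- simulationConfig(nNullSnps = 200)
study <- simulateStudy(cfg, seed = 1)
sum(is.na(study$visitsMissing$visit3))
#> [1] 117

## impute visit 3 from the pre-treatment average, relatives, and the
## fitted bivariate polygenic model
res <- imputeVisit3(study$visitsMissing, study$phi)
res$vc
#> Bivariate polygenic variance components
#>   sigmaA: [0.2907 0.3075; 0.3075 0.4601]
#>   sigmaE: [0.8471 0.6458; 0.6458 0.8589]
#>   heritability: 0.255 / 0.349;  phenotypic correlation: 0.778
#>   log-likelihood: -1610.5311 (n observed values = 1243)

## association on the completed data
y    <- computeOutcome(res$visits, "average_difference")
null <- fitNullModel(y, study$phi)
scan <- scanGenotypes(null, study$G)
head(scan[order(scan$p), c("snp", "beta", "stat", "p")], 3)
#>       snp      beta     stat            p
#> 1 causal1 0.3449948 68.32906 1.383670e-16
#> 2 causal2 0.2873820 48.64810 3.062646e-12
#> 3 causal3 0.2346536 34.55792 4.137539e-09
```

The fitted components recover the panel's generating phenotypic
correlation (about 0.82 after visit noise; estimated 0.78 on this
replicate), and the simulated causal SNPs — explaining 12.5% down to
2.5% of the outcome variance — surface at the top of the scan. On the same data the complete-case
analysis uses 563 of the 680 samples; the evaluation drivers quantify the
corresponding power loss and verify that imputation does not inflate
type-I error.

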