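---
title: "Pedigree-aware conditional MVN phenotype imputation: model and methods"
author: "phenimpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware conditional MVN phenotype imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenimpute)
```

## The problem

Family studies of quantitative traits often lose a substantial share of
their sample to phenotype missingness — expensive assays, loss to follow-up,
or visits that simply did not happen. Dropping incomplete observations
("complete-case analysis") shrinks the sample and with it the power of a
genome-wide association scan. When a second, correlated phenotype has been
measured, and when the missing individual has phenotyped relatives, both
sources of information can be used to reconstruct the missing values.

`phenimpute` implements this idea for the bivariate case: two phenotypes
measured on `n` individuals connected by pedigrees, with gaps allowed in
either phenotype. Missing entries are replaced by their conditional
expectation under a multivariate normal model whose covariance encodes both
the genetic relationships between individuals and the genetic and
environmental correlation between the two phenotypes. Association testing
then proceeds on the completed data with a linear mixed model carrying a
pedigree random effect.

## The model

Stack the two phenotypes into a vector `Y` of length `2n` (phenotype-major:
all individuals for phenotype 1, then all for phenotype 2). The model is

    Y ~ MVN(mu, Sigma),     Sigma = Sigma_A (x) phi + Sigma_E (x) I

where `(x)` is the Kronecker product, `phi` is the `n x n` genetic
relationship matrix derived from the pedigree (or estimated from
genotypes), `Sigma_A` is the 2 x 2 additive-genetic covariance of the two
phenotypes, and `Sigma_E` the 2 x 2 environmental covariance, independent
across individuals. `mu` holds one scalar mean per phenotype, estimated as
the observed mean of that phenotype.

Partitioning `Y` into its missing block `Y_m` and observed block `Y_o`
(with matching mean and covariance blocks), the imputed values are the
conditional expectation

    E(Y_m | Y_o) = mu_m + Sigma_mo Sigma_oo^{-1} (Y_o - mu_o)

This is the best linear predictor: for an individual with no observed data
and no phenotyped relatives it degenerates to the phenotype mean; with an
observed second phenotype it adds the within-individual regression; with
phenotyped relatives it borrows strength in proportion to kinship.

### The relationship matrix convention

`computePhi()` returns the *numerator relationship* matrix: twice the
kinship coefficient, so the diagonal is 1 for non-inbred individuals and a
parent–offspring pair scores 0.5. With this convention `Sigma_A` is
directly the additive-genetic covariance (the parameterization used by
variance-component software such as SOLAR). Users accustomed to kinship
matrices (diagonal 0.5) should multiply by two before passing them in.
Inbreeding is supported by the recursion — the diagonal then exceeds 1 —
but the bundled simulator never generates inbred pedigrees.

### Variance-component estimation

`fitBivariatePolygenic()` maximizes the observed-data likelihood: the MVN
log-density of the observed entries under the restriction of `Sigma` to
observed rows and columns. Missing data therefore enter exactly, without
EM. Choices worth knowing about:

* **ML, not REML.** The per-phenotype means are the observed means, held
  fixed while `Sigma_A`, `Sigma_E` are optimized; the usual small-sample
  downward bias of ML variance estimates applies. At the study sizes the
  package targets (hundreds of families) the bias is negligible next to
  sampling error, which the test suite verifies by parameter-recovery
  simulation.
* **Positive semidefiniteness by construction.** Each 2 x 2 matrix is
  parameterized through its Cholesky factor with log-diagonal (6 free
  parameters), so every candidate point is PSD and heritabilities always
  land in [0, 1].
* **Optimization.** Quasi-Newton (L-BFGS-B, projected-gradient tolerance
  1e-6) from a moment start (complete-pair covariance split 40/60 into
  genetic and environmental parts) plus `nRestarts` deterministic random
  perturbations of it (default 5; the evaluation drivers default to 1,
  which on the well-conditioned simulated likelihoods reaches the same
  optimum — the suite checks that the fitted likelihood dominates the
  generating truth).
* **Block decomposition.** `Sigma` is block-diagonal over the connected
  families of `phi`, so the likelihood is a sum of small per-family MVN
  densities; families sharing a (relationship block, missingness pattern)
  signature share one Cholesky factorization. This is what makes
  re-estimating variance components inside every simulation replicate
  affordable.
* **Identifiability.** When `phi = I` (no relatives) only
  `Sigma_A + Sigma_E` is identified; the fit warns and downstream
  imputation, which depends only on the total in that case, is unaffected.

### Imputation details

* Conditioning is performed family block by family block, which is exactly
  equivalent to conditioning the full joint distribution (verified against
  a dense brute-force oracle in the tests).
* `Sigma_oo` is solved through a symmetric Cholesky factorization, never an
  explicit inverse. If the factorization fails, a diagonal jitter of
  `1e-8 * mean(diag(Sigma_oo))` is added and escalated tenfold at most three
  times before a hard error naming the offending entries; this keeps 80%
  missingness numerically safe.
* Imputation is *single and deterministic*: the conditional mean is
  plugged in once, as a point value. The conditional variance of every
  imputed entry is recorded (`conditionalVarDiag()`) as a diagnostic, but
  downstream tests do not propagate it — association on imputed data
  therefore treats imputed values as if observed, understating their
  uncertainty. That understatement is a property of the method being
  evaluated, not corrected here; the type-I error driver exists precisely
  to check that it stays harmless under the null.
* For four-visit tables, deterministic carry-over fill of the two
  pre-treatment visits (each copied from the other when one is missing)
  runs *before* variance components are estimated, so the MVN machinery
  sees all deterministic completions; model-based imputation then handles
  the post-treatment gaps. A sample missing both pre-treatment visits is a
  hard error, mirroring the rule's precondition.

## Association testing

`fitNullModel()` fits `y ~ N(1 b0, tau * phi + sigma2 * I)` by ML, using
one eigendecomposition of `phi` and a profiled 1-D search over the variance
ratio, then `scoreTest()`/`scanGenotypes()` compute the 1-df score test of
each SNP against that single null fit (additive 0/1/2 coding, no
covariates, one SNP at a time). The score statistic needs no per-SNP model
refit, which is what makes 1e5-test calibration studies cheap. Monomorphic
SNPs return `p = NA` with a flag rather than an error. No multiple-testing
correction is applied; significance thresholds are the caller's.

Two outcome definitions for four-visit designs are built in:
`average_difference` (mean of visits 1–2 minus mean of visits 3–4, on the
log scale) and `single_difference` (visit 1 minus visit 3). Averaging the
replicate visits reduces measurement noise, which is why the
average-difference outcome is consistently more powerful.

## The synthetic study generator

No real family data ship with the package; `simulationConfig()` +
`simulateStudy()` generate studies with the structure the evaluations
need. The defaults are the package's reference study conditions:

| parameter | default | why |
|---|---|---|
| families | 170 nuclear families of 4 (680 samples) | a realistic mid-size family GWAS panel |
| latent phenotypes | unit variance, heritability 0.3 | typical for treatment-response traits |
| visit correlations | 0.9 within period, 0.8 across periods | the two correlation regimes the accuracy evaluation contrasts |
| causal SNPs | 5, MAF 0.3, variance explained 0.125/0.10/0.075/0.05/0.025 | a ladder spanning strong to weak effects |
| missingness | 17.2% of visit 3, MCAR | matches a complete-case loss of 680 to 563 samples |
| replicates | 200 | enough for two-digit power estimates |

Genotypes are gene-dropped: founder alleles iid Bernoulli(MAF), children
inheriting one uniformly chosen allele per parent — so genotype
correlations reproduce `phi` by construction, which the tests verify.
Causal effects are added to the post-treatment latent phenotype with sign
chosen so the pre-minus-post outcome increases with dosage, and effect
sizes solve `beta^2 * 2 maf (1-maf) = v * Var(outcome)` exactly, so SNP
`j`'s marginal share of outcome variance is its nominal `v_j`.

Visit-level measurements add iid noise to the latent phenotypes; the noise
variance is solved from the within-period correlation target, and the
latent cross-phenotype correlation is `corCross / corPre` so both targets
are hit simultaneously (configurations with `corCross > corPre` are
rejected as infeasible). Missingness is MCAR only, with an exact
round-half-up count of masked entries; informative missingness is out of
scope.

What the generator does *not* emulate: linkage disequilibrium, haplotype
structure, population stratification, covariate effects (age, sex,
center), non-normal phenotype scales, and the particular pedigree-size
mixture and treatment-response simulation model of real consortium data.
Passing evaluations on this surrogate therefore demonstrate the method's
internal correctness and calibration, not its absolute performance numbers
on any real study. One visible consequence: with 680 samples and variance
explained interpreted on the analyzed outcome, the power ladder sits near
1 at most rungs — real studies, where the stated variance share refers to
an underlying response variable diluted by additional noise, land much
lower. The qualitative contrasts (imputed vs incomplete, averaged vs
single-visit outcomes, monotonicity in effect size) are the meaningful
read-outs here.

## The evaluation drivers

* `runType1()` pools score-test p-values of null SNPs over replicates and
  reports rejection rates with binomial Monte-Carlo standard errors, for
  both outcomes on the incomplete and imputed datasets. The incomplete
  dataset drops every sample missing a post-treatment visit; the imputed
  dataset completes visit 3 via the full pipeline, re-estimating variance
  components within each replicate.
* `runPower()` does the same for the causal-SNP ladder at alpha = 0.01 and
  1e-4.
* `runMSE()` masks 20/50/80% of visit-2 values, imputes them once from
  visit 1 (correlation 0.9) and once from visit 4 (correlation 0.8) with
  the same mask, and reports the mean squared error over masked entries.
  For unrelated individuals with unit-variance phenotypes the theoretical
  MSE is `Var(visit) * (1 - rho^2)`, so the 0.8 : 0.9 ratio should
  approach `(1 - 0.64)/(1 - 0.81) = 1.89` — the acceptance suite checks
  this closed form, and that the MSE moves by less than 10% across missing
  fractions.

Problem sizes in the shipped acceptance runs are chosen to keep each
driver to a few minutes on one core: 2,000 null SNPs x 50 replicates
(1e5 pooled null tests) for type-I error, 200 replicates for power and
MSE, and restart counts of 0–2 in the drivers (see above). All drivers are
deterministic given `(config, seed)` and derive per-replicate seeds from
one master seed.

## Known limitations

* Exactly two phenotypes; more would require generalizing the 2 x 2
  component matrices (the covariance algebra would carry over unchanged).
* No fixed-effect covariates in either the polygenic model or the
  association model.
* Single deterministic imputation understates downstream variance, as
  discussed; multiple imputation and drawing from the conditional
  distribution are deliberately out of scope.
* ML bias at very small family counts; the moment start assumes at least a
  handful of complete pairs.
* No household/shared-environment variance component, no X-chromosome or
  IBD-segment relatedness estimators.
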