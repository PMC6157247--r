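## Synthetic family-study generator: pedigrees, gene-dropped genotypes,
## bivariate / four-visit phenotypes, and MCAR missingness.

#' Simulation configuration
#'
#' Collects the study conditions for the synthetic family-study generator.
#' Defaults emulate the treatment-response design the evaluations target:
#' 170 nuclear families of 4 (680 study samples), two latent log-scale
#' phenotypes (pre- and post-treatment) of unit total variance with
#' heritability 0.3, visit-level replicate measurements whose
#' within-treatment correlation is 0.9 and cross-treatment correlation 0.8,
#' five causal SNPs explaining 0.125/0.10/0.075/0.05/0.025 of the outcome
#' variance, and 17.2% missingness of the first post-treatment visit
#' (missing completely at random).
#'
#' @param nFamilies number of families.
#' @param template family template: \code{"nuclear_4"} (2 founders + 2
#'   children, all in the study), \code{"sib_pair"} (2 study sibs connected
#'   through 2 untyped founder parents), \code{"three_gen_8"} (4
#'   grandparents, 2 parents, 2 children), or \code{"singleton"} (unrelated
#'   individuals).
#' @param nNullSnps number of SNPs simulated with no phenotype effect.
#' @param nullMafRange range the null-SNP minor-allele frequencies are drawn
#'   from (uniform).
#' @param causal data.frame with columns \code{maf} and \code{varExplained}
#'   describing causal SNPs; their summed variance explained must be < 1.
#' @param h2 narrow-sense heritability of each latent phenotype.
#' @param totalVar total variance of each latent phenotype.
#' @param corPre target correlation between the two replicate visits of one
#'   treatment period (e.g. visit 1 vs visit 2).
#' @param corCross target correlation between visits of different treatment
#'   periods (e.g. visit 2 vs visit 4); must not exceed \code{corPre}.
#' @param missingFraction fraction of visit-3 values masked MCAR.
#' @param nReplicates default number of simulation replicates for the
#'   evaluation drivers.
#' @return list of class \code{"simulationConfig"}.
#' @export
simulationConfig <- function(nFamilies = 170L,
                             template = c("nuclear_4", "sib_pair",
                                          "three_gen_8", "singleton"),
                             nNullSnps = 0L,
                             nullMafRange = c(0.05, 0.5),
                             causal = data.frame(
                               maf = rep(0.3, 5),
                               varExplained = c(0.125, 0.10, 0.075,
                                                0.05, 0.025)),
                             h2 = 0.3, totalVar = 1,
                             corPre = 0.9, corCross = 0.8,
                             missingFraction = 0.172,
                             nReplicates = 200L) {
  template <- match.arg(template)
  if (!is.null(causal) && nrow(causal)) {
    stopifnot(all(causal$maf > 0 & causal$maf <= 0.5),
              sum(causal$varExplained) < 1,
              all(causal$varExplained >= 0))
  }
  stopifnot(corPre > 0, corPre < 1, corCross >= 0, corCross <= corPre,
            h2 >= 0, h2 < 1, missingFraction >= 0, missingFraction < 1)
  structure(list(nFamilies = as.integer(nFamilies), template = template,
                 nNullSnps = as.integer(nNullSnps),
                 nullMafRange = nullMafRange, causal = causal,
                 h2 = h2, totalVar = totalVar,
                 corPre = corPre, corCross = corCross,
                 missingFraction = missingFraction,
                 nReplicates = as.integer(nReplicates)),
            class = "simulationConfig")
}

#' @export
print.simulationConfig <- function(x, ...) {
  cat(sprintf("simulationConfig: %d x %s families, %d null SNPs, %d causal SNPs\n",
              x$nFamilies, x$template, x$nNullSnps,
              if (is.null(x$causal)) 0L else nrow(x$causal)))
  cat(sprintf("  h2 = %.2f, corPre = %.2f, corCross = %.2f, missing = %.3f\n",
              x$h2, x$corPre, x$corCross, x$missingFraction))
  invisible(x)
}

## True variance components implied by a config: equal genetic and
## environmental cross-correlation, so the latent phenotypic correlation is
## corCross / corPre (what the visit-noise model needs to hit both targets).
.configTrueVC <- function(config) {
  rho <- config$corCross / config$corPre
  C <- matrix(c(1, rho, rho, 1), 2, 2) * config$totalVar
  VarianceComponents(sigmaA = config$h2 * C, sigmaE = (1 - config$h2) * C)
}

#' True variance components implied by a simulation configuration
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{VarianceComponents} (the generating truth).
#' @export
trueVarianceComponents <- function(config) .configTrueVC(config)

#' Simulate disjoint template families
#'
#' @param nFamilies number of family copies.
#' @param template see \code{\link{simulationConfig}}.
#' @return a \linkS4class{Pedigree}; ids are \code{F<k>_<role>}.
#' @export
simulatePedigrees <- function(nFamilies,
                              template = c("nuclear_4", "sib_pair",
                                           "three_gen_8", "singleton")) {
  template <- match.arg(template)
  tpl <- switch(template,
    singleton = data.frame(role = "i1", dad = NA, mom = NA,
                           sex = 1L, phenotyped = TRUE),
    nuclear_4 = data.frame(
      role = c("dad", "mom", "c1", "c2"),
      dad = c(NA, NA, "dad", "dad"), mom = c(NA, NA, "mom", "mom"),
      sex = c(1L, 2L, 1L, 2L), phenotyped = TRUE),
    sib_pair = data.frame(
      role = c("dad", "mom", "s1", "s2"),
      dad = c(NA, NA, "dad", "dad"), mom = c(NA, NA, "mom", "mom"),
      sex = c(1L, 2L, 1L, 2L),
      phenotyped = c(FALSE, FALSE, TRUE, TRUE)),
    three_gen_8 = data.frame(
      role = c("gp1", "gp2", "gp3", "gp4", "dad", "mom", "c1", "c2"),
      dad = c(NA, NA, NA, NA, "gp1", "gp3", "dad", "dad"),
      mom = c(NA, NA, NA, NA, "gp2", "gp4", "mom", "mom"),
      sex = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L), phenotyped = TRUE))
  fam <- rep(sprintf("F%04d", seq_len(nFamilies)), each = nrow(tpl))
  role <- rep(tpl$role, nFamilies)
  id <- paste0(fam, "_", role)
  pid <- function(p) ifelse(is.na(p), NA_character_, paste0(fam, "_", p))
  Pedigree(famID = fam, id = id,
           dadID = pid(rep(tpl$dad, nFamilies)),
           momID = pid(rep(tpl$mom, nFamilies)),
           sex = rep(tpl$sex, nFamilies),
           phenotyped = rep(tpl$phenotyped, nFamilies))
}

#' Gene-drop genotypes down a pedigree
#'
#' Simulates additive dosages by Mendelian transmission: founder alleles are
#' iid Bernoulli(maf) and each child inherits one uniformly chosen allele
#' from each parent, independently per variant.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param maf minor-allele frequency, a scalar or a vector of length
#'   \code{nVariants} (values in (0, 0.5]).
#' @param nVariants number of independent variants to drop.
#' @param seed optional seed (the caller's RNG state is preserved).
#' @return integer dosage matrix, pedigree members in rows (rownames = ids),
#'   variants in columns.
#' @export
geneDrop <- function(ped, maf, nVariants = 1L, seed = NULL) {
  stopifnot(all(maf > 0), all(maf <= 0.5))
  p <- rep_len(maf, nVariants)
  m <- pedMembers(ped)
  ord <- .pedigreeTopoOrder(m)
  n <- nrow(m)
  dad <- match(m$dadID, m$id)
  mom <- match(m$momID, m$id)
  .withSeed(seed, {
    hap1 <- matrix(0L, n, nVariants)
    hap2 <- matrix(0L, n, nVariants)
    for (i in ord) {
      if (is.na(dad[i])) {
        hap1[i, ] <- rbinom(nVariants, 1L, p)
      } else {
        pick <- runif(nVariants) < 0.5
        hap1[i, ] <- ifelse(pick, hap1[dad[i], ], hap2[dad[i], ])
      }
      if (is.na(mom[i])) {
        hap2[i, ] <- rbinom(nVariants, 1L, p)
      } else {
        pick <- runif(nVariants) < 0.5
        hap2[i, ] <- ifelse(pick, hap1[mom[i], ], hap2[mom[i], ])
      }
    }
    G <- hap1 + hap2
    rownames(G) <- m$id
    colnames(G) <- paste0("snp", seq_len(nVariants))
    G
  })
}

#' Draw bivariate polygenic phenotypes
#'
#' Samples the stacked phenotype vector from
#' \code{MVN(mu + meanShift, sigmaA \%x\% phi + sigmaE \%x\% I)}, exploiting
#' the block-diagonal structure over the family components of phi (identical
#' family blocks share one Cholesky factor).
#'
#' @param phi relationship matrix of the sampled individuals.
#' @param vc generating \linkS4class{VarianceComponents}.
#' @param mu numeric(2) per-phenotype means.
#' @param meanShift optional n x 2 matrix added to the mean (e.g. genotype
#'   effects).
#' @param seed optional seed.
#' @return a fully observed \linkS4class{PhenotypePanel}.
#' @export
simulatePhenotypes <- function(phi, vc, mu = c(0, 0), meanShift = NULL,
                               seed = NULL) {
  n <- nrow(phi)
  ids <- rownames(phi)
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  sA <- sigmaA(vc); sE <- sigmaE(vc)
  comp <- .phiComponents(phi)
  vals <- matrix(0, n, 2L)
  .withSeed(seed, {
    sigs <- vapply(unique(comp), function(cid) {
      idx <- which(comp == cid)
      paste(length(idx), paste(signif(phi[idx, idx], 12), collapse = ","))
    }, character(1))
    cholCache <- list()
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      k <- length(idx)
      sig <- sigs[[match(cid, unique(comp))]]
      if (is.null(cholCache[[sig]])) {
        Sigma <- kronecker(sA, phi[idx, idx, drop = FALSE]) +
          kronecker(sE, diag(k))
        cholCache[[sig]] <- chol(Sigma + diag(1e-10, 2L * k))
      }
      z <- crossprod(cholCache[[sig]], rnorm(2L * k))
      vals[idx, ] <- matrix(z, k, 2L)
    }
    vals <- vals + rep(as.numeric(mu), each = n)
    if (!is.null(meanShift)) vals <- vals + meanShift
    PhenotypePanel(ids = ids, values = vals)
  })
}

#' Expand a latent bivariate panel into four visit-level measurements
#'
#' Visits 1 and 2 are independent noisy replicates of phenotype 1
#' (pre-treatment) and visits 3 and 4 of phenotype 2 (post-treatment):
#' \code{visit = latent + e}, \code{e ~ N(0, noiseVar)} iid. With latent
#' variance V, the within-period visit correlation is \code{V / (V +
#' noiseVar)}; \code{\link{visitNoiseVar}} solves this for a target.
#'
#' @param panel fully observed latent \linkS4class{PhenotypePanel}.
#' @param noiseVar visit-level noise variance.
#' @param seed optional seed.
#' @return data.frame with columns \code{id}, \code{visit1} .. \code{visit4}.
#' @export
simulateVisits <- function(panel, noiseVar, seed = NULL) {
  v <- phenoValues(panel)
  n <- nrow(v)
  .withSeed(seed, {
    e <- matrix(rnorm(4L * n, sd = sqrt(noiseVar)), n, 4L)
    data.frame(id = panelIds(panel),
               visit1 = v[, 1L] + e[, 1L], visit2 = v[, 1L] + e[, 2L],
               visit3 = v[, 2L] + e[, 3L], visit4 = v[, 2L] + e[, 4L],
               stringsAsFactors = FALSE)
  })
}

#' @rdname simulateVisits
#' @param latentVar latent phenotype variance.
#' @param corTarget target within-period visit correlation.
#' @export
visitNoiseVar <- function(latentVar, corTarget) {
  stopifnot(corTarget > 0, corTarget < 1)
  latentVar * (1 - corTarget) / corTarget
}

#' Mask phenotype values completely at random
#'
#' Exactly \code{floor(fraction * n + 0.5)} entries (round half up) of the
#' designated phenotype are set missing, chosen uniformly without
#' replacement; deterministic under \code{seed}.
#'
#' @param panel a \linkS4class{PhenotypePanel}.
#' @param fraction fraction in [0, 1) of values to mask.
#' @param phenotype which phenotype column to mask (1 or 2).
#' @param seed optional seed.
#' @return the masked \linkS4class{PhenotypePanel}.
#' @export
applyMissingness <- function(panel, fraction, phenotype = 2L, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  v <- phenoValues(panel)
  idx <- .maskIndices(nrow(v), fraction, seed)
  v[idx, phenotype] <- NA_real_
  PhenotypePanel(ids = panelIds(panel), values = v,
                 phenoNames = colnames(v))
}

#' @rdname applyMissingness
#' @param visits four-visit data.frame.
#' @param visit name of the visit column to mask.
#' @export
maskVisit <- function(visits, visit, fraction, seed = NULL) {
  idx <- .maskIndices(nrow(visits), fraction, seed)
  visits[[visit]][idx] <- NA_real_
  visits
}

## ---------------------------------------------------------------------------
## Study-level orchestration
## ---------------------------------------------------------------------------

## Fixed part of a simulated study: pedigree, relationship matrix of the
## study sample, genotypes (gene-dropped once; like a real study, genotypes
## stay fixed while phenotype replicates vary), and causal effect sizes.
.studyScaffold <- function(config, seed = NULL) {
  seeds <- .childSeeds(seed, 3L)
  ped <- simulatePedigrees(config$nFamilies, config$template)
  phi <- computePhi(ped, onlyPhenotyped = TRUE)
  nCausal <- if (is.null(config$causal)) 0L else nrow(config$causal)
  nullMafs <- if (config$nNullSnps > 0L)
    .withSeed(seeds[1L], runif(config$nNullSnps, config$nullMafRange[1L],
                               config$nullMafRange[2L])) else numeric(0)
  mafs <- c(if (nCausal) config$causal$maf, nullMafs)
  G <- NULL
  if (length(mafs)) {
    G <- geneDrop(ped, mafs, nVariants = length(mafs), seed = seeds[2L])
    G <- G[studyIds(ped), , drop = FALSE]
    colnames(G) <- c(if (nCausal) paste0("causal", seq_len(nCausal)),
                     if (config$nNullSnps > 0L)
                       paste0("null", seq_len(config$nNullSnps)))
  }
  ## Effect sizes: the average-difference outcome is the designated trait.
  ## Its variance without SNPs is 2 V (1 - rho) + noiseVar; beta_j is sized
  ## so that SNP j's marginal share of the total outcome variance is v_j.
  noiseVar <- visitNoiseVar(config$totalVar, config$corPre)
  rho <- config$corCross / config$corPre
  varBase <- 2 * config$totalVar * (1 - rho) + noiseVar
  beta <- numeric(0)
  if (nCausal) {
    v <- config$causal$varExplained
    varTotal <- varBase / (1 - sum(v))
    beta <- sqrt(v * varTotal / (2 * config$causal$maf * (1 - config$causal$maf)))
  }
  list(ped = ped, phi = phi, G = G, beta = beta, noiseVar = noiseVar,
       vcTrue = .configTrueVC(config), config = config)
}

## One phenotype replicate on a fixed scaffold: latent bivariate panel with
## causal effects subtracted from the post-treatment phenotype (so the
## pre-minus-post outcome increases with dosage), then four visits.
.simulateReplicate <- function(scaffold, seed = NULL) {
  seeds <- .childSeeds(seed, 2L)
  shift <- NULL
  if (length(scaffold$beta)) {
    Gc <- scaffold$G[, seq_along(scaffold$beta), drop = FALSE]
    shift <- cbind(0, -as.numeric(Gc %*% scaffold$beta))
  }
  panel <- simulatePhenotypes(scaffold$phi, scaffold$vcTrue,
                              meanShift = shift, seed = seeds[1L])
  visits <- simulateVisits(panel, scaffold$noiseVar, seed = seeds[2L])
  list(latent = panel, visits = visits)
}

#' Simulate one complete synthetic family study
#'
#' Generates pedigree, relationship matrix, gene-dropped genotypes (causal
#' SNPs first, then null SNPs), a latent bivariate phenotype panel, the
#' four-visit expansion, and the MCAR visit-3 missingness of the
#' configuration. Fully deterministic given \code{(config, seed)}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return list with \code{ped}, \code{phi} (study individuals), \code{G}
#'   (study x SNP dosages), \code{latent} (complete
#'   \linkS4class{PhenotypePanel}), \code{visits} (complete four-visit
#'   data.frame), \code{visitsMissing} (after masking), \code{beta} (causal
#'   effect sizes) and \code{vcTrue}.
#' @export
simulateStudy <- function(config, seed = 1L) {
  seeds <- .childSeeds(seed, 3L)
  sc <- .studyScaffold(config, seed = seeds[1L])
  rep1 <- .simulateReplicate(sc, seed = seeds[2L])
  vm <- maskVisit(rep1$visits, "visit3", config$missingFraction,
                  seed = seeds[3L])
  list(ped = sc$ped, phi = sc$phi, G = sc$G, latent = rep1$latent,
       visits = rep1$visits, visitsMissing = vm, beta = sc$beta,
       vcTrue = sc$vcTrue, config = config)
}
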