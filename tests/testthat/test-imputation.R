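test_that("block partition is index-consistent and reassembles Sigma", {
  vc <- VarianceComponents(sigmaA = matrix(c(1, .4, .4, 1), 2, 2),
                           sigmaE = matrix(c(1, .2, .2, 1), 2, 2))
  phi <- computePhi(simulatePedigrees(1, "nuclear_4"))
  Sigma <- buildJointCovariance(vc, phi)

  ## nothing missing: observed block is all of Sigma
  pFull <- PhenotypePanel(rownames(phi), matrix(1, 4, 2))
  pb <- partitionBlocks(pFull, c(0, 0), Sigma)
  expect_length(pb$muM, 0)
  expect_equal(pb$SigmaOO, Sigma)

  ## phenotype 2 fully missing: cross block is the (2,1) Kronecker block
  p2m <- PhenotypePanel(rownames(phi), cbind(1:4, NA))
  pb2 <- partitionBlocks(p2m, c(0, 0), Sigma)
  expect_equal(unname(pb2$SigmaMO), unname(Sigma[5:8, 1:4]))

  ## random masks: blocks reassemble Sigma exactly
  withr::with_seed(8, {
    for (i in 1:10) {
      v <- matrix(rnorm(10), 5, 2)
      v[sample(10, sample(1:9, 1))] <- NA
      phi5 <- computePhi(simulatePedigrees(1, "three_gen_8"))[1:5, 1:5]
      p <- PhenotypePanel(rownames(phi5), v)
      S5 <- buildJointCovariance(vc, phi5)
      pb <- partitionBlocks(p, c(.1, .2), S5)
      rebuilt <- matrix(NA_real_, 10, 10)
      idx <- c(pb$missIdx, pb$obsIdx)
      rebuilt[idx, idx] <- rbind(cbind(pb$SigmaMM, pb$SigmaMO),
                                 cbind(t(pb$SigmaMO), pb$SigmaOO))
      expect_equal(rebuilt, unname(S5))
    }
  })
})

test_that("conditional mean matches closed forms and the brute-force oracle", {
  ## zero cross-covariance degenerates to the unconditional mean
  expect_equal(conditionalMean(muM = c(3, 4), muO = 0,
                               SigmaMO = matrix(0, 2, 1),
                               SigmaOO = matrix(1), yO = 5),
               c(3, 4))

  ## bivariate normal regression: mu1 + rho*(sigma1/sigma2)*(y2 - mu2)
  imp <- conditionalMean(muM = 0, muO = 0, SigmaMO = matrix(0.8, 1, 1),
                         SigmaOO = matrix(1), yO = 1.0)
  expect_equal(imp, 0.8)

  ## nuclear family, arbitrary PSD Sigma, 3 random missing entries
  withr::with_seed(21, {
    phi <- computePhi(simulatePedigrees(1, "nuclear_4"))
    vc <- VarianceComponents(sigmaA = random2x2(), sigmaE = random2x2())
    Sigma <- buildJointCovariance(vc, phi)
    v <- matrix(rnorm(8), 4, 2)
    v[sample(8, 3)] <- NA
    p <- PhenotypePanel(rownames(phi), v)
    pb <- partitionBlocks(p, c(0, 0), Sigma)
    got <- conditionalMean(pb$muM, pb$muO, pb$SigmaMO, pb$SigmaOO, pb$yO)
    expect_equal(got, bruteConditionalOracle(p, c(0, 0), Sigma),
                 tolerance = 1e-10)
  })
})

test_that("imputePanel equals full-joint conditioning and keeps observed bits", {
  withr::with_seed(99, {
    for (i in 1:8) {
      inst <- randomInstance(maxFamilies = 3)
      mu <- c(0.3, -0.2)
      imp <- imputePanel(inst$panel, inst$vc, inst$phi, mu = mu)
      Sigma <- buildJointCovariance(inst$vc, inst$phi)
      oracle <- bruteConditionalOracle(inst$panel, mu, Sigma)
      y <- stackedY(inst$panel)
      expect_equal(stackedY(imp)[is.na(y)], oracle, tolerance = 1e-8)
      expect_identical(stackedY(imp)[!is.na(y)], y[!is.na(y)])
      expect_false(anyNA(phenoValues(imp)))
      expect_true(all(provenance(imp)[is.na(phenoValues(inst$panel))] ==
                        "mvn_imputed"))
    }
  })
})

test_that("fully observed panels pass through; isolated blanks get the mean", {
  phi <- diag(3); dimnames(phi) <- list(c("a", "b", "c"), c("a", "b", "c"))
  vc <- VarianceComponents(sigmaA = matrix(0, 2, 2), sigmaE = diag(2))
  pFull <- PhenotypePanel(c("a", "b", "c"), matrix(rnorm(6), 3, 2))
  impF <- imputePanel(pFull, vc, phi)
  expect_identical(phenoValues(impF), phenoValues(pFull))
  expect_true(all(provenance(impF) == "observed"))

  ## individual c has no data and no relatives; uncorrelated phenotypes
  v <- matrix(c(1, 2, NA, 4, 6, NA), 3, 2)
  p <- PhenotypePanel(c("a", "b", "c"), v)
  imp <- imputePanel(p, vc, phi)
  expect_equal(unname(phenoValues(imp)["c", ]), unname(observedMeans(p)))
})

test_that("near-perfect phenotype correlation gives near-perfect imputation", {
  phi <- diag(50); dimnames(phi) <- list(paste0("i", 1:50), paste0("i", 1:50))
  vc <- VarianceComponents(sigmaA = matrix(0, 2, 2),
                           sigmaE = matrix(c(1, 1 - 1e-8, 1 - 1e-8, 1), 2, 2))
  x <- withr::with_seed(3, rnorm(50))
  v <- cbind(x, x); v[1:20, 2] <- NA
  p <- PhenotypePanel(paste0("i", 1:50), v)
  imp <- imputePanel(p, vc, phi, mu = c(0, 0))
  expect_equal(unname(phenoValues(imp)[1:20, 2]), x[1:20], tolerance = 1e-3)
})

test_that("hidden-entry imputations correlate with the truth at rho = 0.9", {
  ped <- simulatePedigrees(150, "nuclear_4")
  phi <- computePhi(ped)
  C <- matrix(c(1, .9, .9, 1), 2, 2)
  vcTrue <- VarianceComponents(0.3 * C, 0.7 * C)
  panel <- simulatePhenotypes(phi, vcTrue, seed = 14)
  truth <- phenoValues(panel)[, 2]
  masked <- applyMissingness(panel, 0.3, phenotype = 2, seed = 15)
  idx <- which(is.na(phenoValues(masked)[, 2]))
  fit <- fitBivariatePolygenic(masked, phi, nRestarts = 1)
  imp <- imputePanel(masked, fit, phi)
  expect_gt(cor(phenoValues(imp)[idx, 2], truth[idx]), 0.7)
  ## conditional-variance diagnostic present exactly on imputed entries
  cv <- conditionalVarDiag(imp)
  expect_true(all(is.finite(cv[idx, 2])))
  expect_true(all(is.na(cv[-idx, 2])))
})

test_that("observing more relatives never increases conditional variance", {
  withr::with_seed(55, {
    phi <- computePhi(simulatePedigrees(1, "three_gen_8"))
    vc <- VarianceComponents(sigmaA = random2x2(), sigmaE = random2x2())
    Sigma <- buildJointCovariance(vc, phi)
    for (i in 1:6) {
      obs <- sample(16, sample(4:12, 1))
      target <- sample(setdiff(1:16, obs), 1)
      extra <- sample(setdiff(1:16, c(obs, target)), 1)
      cv <- function(o) {
        S <- Sigma[target, target] -
          Sigma[target, o, drop = FALSE] %*%
            solve(Sigma[o, o, drop = FALSE], Sigma[o, target, drop = FALSE])
        as.numeric(S)
      }
      expect_lte(cv(c(obs, extra)), cv(obs) + 1e-10)
    }
  })
})

test_that("with identity phi an individual's imputation uses only its own data", {
  phi <- diag(6); dimnames(phi) <- list(paste0("i", 1:6), paste0("i", 1:6))
  vc <- VarianceComponents(sigmaA = matrix(0, 2, 2),
                           sigmaE = matrix(c(1, .6, .6, 1), 2, 2))
  v <- withr::with_seed(2, matrix(rnorm(12), 6, 2))
  v[3, 2] <- NA
  p <- PhenotypePanel(paste0("i", 1:6), v)
  mu <- observedMeans(p)
  imp1 <- phenoValues(imputePanel(p, vc, phi, mu = mu))[3, 2]
  v2 <- v; v2[5, ] <- v2[5, ] + 10   # perturb an unrelated sample
  imp2 <- phenoValues(imputePanel(PhenotypePanel(paste0("i", 1:6), v2),
                                  vc, phi, mu = mu))[3, 2]
  expect_equal(imp1, imp2)
})

test_that("carry-over fill copies between the pre-treatment visits", {
  visits <- data.frame(id = c("a", "b", "c"),
                       visit1 = c(NA, 4.1, 4.3), visit2 = c(4.7, NA, 4.2),
                       visit3 = c(3.9, 3.8, NA), visit4 = c(3.7, 3.6, 3.5))
  out <- carryoverFill(visits)
  expect_equal(out$visits$visit1[1], 4.7)
  expect_equal(out$visits$visit2[2], 4.1)
  expect_equal(out$provenance["a", "visit1"], "carryover_filled")
  expect_equal(out$provenance["b", "visit1"], "observed")
  ## untouched rows unchanged
  expect_equal(out$visits[3, c("visit1", "visit2")],
               visits[3, c("visit1", "visit2")])
  ## both pre-treatment visits missing violates the precondition
  bad <- visits; bad$visit1[1] <- NA; bad$visit2[1] <- NA
  expect_error(carryoverFill(bad), "both visit 1 and visit 2")
})
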