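test_that("joint covariance reproduces the Kronecker structure", {
  ## sigmaA = 0: block-diagonal per individual
  vc0 <- VarianceComponents(sigmaA = matrix(0, 2, 2),
                            sigmaE = matrix(c(1, .3, .3, 2), 2, 2))
  phi <- computePhi(simulatePedigrees(1, "nuclear_4"))
  S <- buildJointCovariance(vc0, phi)
  expect_equal(unname(S), kronecker(matrix(c(1, .3, .3, 2), 2, 2), diag(4)))

  ## two founders, sigmaA = sigmaE = I: Sigma = 2 I
  vcI <- VarianceComponents(diag(2), diag(2))
  phiI <- diag(2); dimnames(phiI) <- list(c("a", "b"), c("a", "b"))
  expect_equal(unname(buildJointCovariance(vcI, phiI)), 2 * diag(4))

  ## parent-offspring, only phenotype-1 variance: block (1,1) from hand
  ## Kronecker expansion
  po <- Pedigree("F", c("p", "c"), c(NA, "p"), c(NA, NA))
  phiPO <- computePhi(po)
  vc1 <- VarianceComponents(sigmaA = matrix(c(1, 0, 0, 0), 2, 2),
                            sigmaE = matrix(c(1, 0, 0, 0), 2, 2))
  S1 <- buildJointCovariance(vc1, phiPO)
  expect_equal(unname(S1[1:2, 1:2]), matrix(c(2, .5, .5, 2), 2, 2))
  expect_equal(unname(S1[3:4, 3:4]), matrix(0, 2, 2))
})

test_that("observed means use observed entries only", {
  p <- PhenotypePanel(ids = c("a", "b", "c", "d"),
                      pheno1 = c(1, 2, NA, 3), pheno2 = c(5, 5, 5, 5))
  expect_equal(unname(observedMeans(p)), c(2, 5))
  pc <- PhenotypePanel(ids = "a", pheno1 = 7, pheno2 = NA)
  expect_error(observedMeans(pc), "no observed")
})

test_that("log-likelihood matches elementary cases and is order-invariant", {
  ## single individual, one observed standard-normal phenotype
  phi1 <- matrix(1, dimnames = list("a", "a"))
  p1 <- PhenotypePanel(ids = "a", pheno1 = 0, pheno2 = NA)
  vc <- VarianceComponents(sigmaA = 0.4 * diag(2), sigmaE = 0.6 * diag(2))
  expect_equal(polygenicLoglik(vc, c(0, 0), p1, phi1), -0.5 * log(2 * pi))

  ## permutation of individuals leaves the value unchanged
  withr::with_seed(11, {
    inst <- randomInstance(maxFamilies = 2)
    ll <- polygenicLoglik(inst$vc, inst$mu, inst$panel, inst$phi)
    perm <- sample(length(panelIds(inst$panel)))
    p2 <- PhenotypePanel(panelIds(inst$panel)[perm],
                         phenoValues(inst$panel)[perm, ])
    ll2 <- polygenicLoglik(inst$vc, inst$mu, p2,
                           inst$phi[perm, perm, drop = FALSE])
    expect_equal(ll2, ll)
  })
})

test_that("block-decomposed likelihood equals the dense MVN oracle (2n <= 24)", {
  withr::with_seed(202, {
    for (i in 1:12) {
      inst <- randomInstance(maxFamilies = 3)
      if (2 * length(panelIds(inst$panel)) > 24) next
      ll <- polygenicLoglik(inst$vc, inst$mu, inst$panel, inst$phi)
      expect_equal(ll, denseLoglikOracle(inst$vc, inst$mu, inst$panel,
                                         inst$phi),
                   tolerance = 1e-8)
    }
  })
})

test_that("likelihood is scale-equivariant", {
  withr::with_seed(31, {
    inst <- randomInstance(maxFamilies = 2)
    nObs <- sum(!is.na(phenoValues(inst$panel)))
    ll <- polygenicLoglik(inst$vc, inst$mu, inst$panel, inst$phi)
    vc2 <- VarianceComponents(2 * sigmaA(inst$vc), 2 * sigmaE(inst$vc))
    p2 <- PhenotypePanel(panelIds(inst$panel),
                         sqrt(2) * phenoValues(inst$panel))
    ll2 <- polygenicLoglik(vc2, sqrt(2) * inst$mu, p2, inst$phi)
    ## doubling Sigma while scaling Y by sqrt(2) only shifts the Jacobian
    expect_equal(ll2, ll - nObs * log(2) / 2)
  })
})

test_that("ML fit drives genetic variance to zero on non-heritable data", {
  ped <- simulatePedigrees(300, "sib_pair")
  phi <- computePhi(ped, onlyPhenotyped = TRUE)
  vcTrue <- VarianceComponents(sigmaA = matrix(0, 2, 2),
                               sigmaE = matrix(c(1, .5, .5, 1), 2, 2))
  a11 <- withr::with_seed(77, replicate(7, {
    p <- simulatePhenotypes(phi, vcTrue)
    fit <- fitBivariatePolygenic(p, phi, nRestarts = 1)
    sigmaA(fit)[1, 1] / (sigmaA(fit)[1, 1] + sigmaE(fit)[1, 1])
  }))
  expect_lt(median(a11), 0.1)
})

test_that("fitted log-likelihood dominates the generating parameters", {
  ped <- simulatePedigrees(60, "nuclear_4")
  phi <- computePhi(ped)
  vcTrue <- VarianceComponents(sigmaA = matrix(c(1, .5, .5, 1), 2, 2),
                               sigmaE = matrix(c(1, .3, .3, 1), 2, 2))
  withr::with_seed(5, {
    for (i in 1:3) {
      p <- applyMissingness(simulatePhenotypes(phi, vcTrue), 0.2)
      fit <- fitBivariatePolygenic(p, phi, nRestarts = 2)
      mu <- observedMeans(p)
      expect_gte(fittedLoglik(fit) + 1e-6,
                 polygenicLoglik(vcTrue, mu, p, phi))
      h2 <- heritability(fit)
      expect_true(all(h2 >= 0 & h2 <= 1))
    }
  })
})

test_that("phenotypic correlation is recovered on unrelated samples", {
  phi <- diag(675)
  dimnames(phi) <- list(paste0("i", 1:675), paste0("i", 1:675))
  for (rho in c(0.9, 0.8)) {
    C <- matrix(c(1, rho, rho, 1), 2, 2)
    vcTrue <- VarianceComponents(0.3 * C, 0.7 * C)
    p <- simulatePhenotypes(phi, vcTrue, seed = round(1000 * rho))
    fit <- suppressWarnings(fitBivariatePolygenic(p, phi, nRestarts = 1))
    expect_lt(abs(phenotypicCorrelation(fit) - rho), 0.05)
  }
})

test_that("identity phi triggers the identifiability warning", {
  phi <- diag(30); dimnames(phi) <- list(paste0("i", 1:30), paste0("i", 1:30))
  p <- simulatePhenotypes(phi, VarianceComponents(0.3 * diag(2), 0.7 * diag(2)),
                          seed = 4)
  expect_warning(fitBivariatePolygenic(p, phi, nRestarts = 0),
                 "identified")
})

test_that("variance components round-trip through the key-value file", {
  vc <- VarianceComponents(sigmaA = matrix(c(1, .5, .5, 1.2), 2, 2),
                           sigmaE = matrix(c(.9, .2, .2, 1.1), 2, 2),
                           loglik = -123.456, nObs = 99L)
  tf <- withr::local_tempfile()
  writeVarianceComponents(vc, tf)
  vc2 <- readVarianceComponents(tf)
  expect_equal(sigmaA(vc2), sigmaA(vc))
  expect_equal(sigmaE(vc2), sigmaE(vc))
  expect_equal(fittedLoglik(vc2), -123.456)
})
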