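test_that("outcomes implement the pre/post visit contrasts", {
  visits <- data.frame(id = "a", visit1 = 4.0, visit2 = 4.2,
                       visit3 = 3.6, visit4 = 3.8)
  expect_equal(as.numeric(computeOutcome(visits, "average_difference")), 0.4)
  expect_equal(as.numeric(computeOutcome(visits, "single_difference")), 0.4)
  flat <- data.frame(id = "a", visit1 = 2, visit2 = 2, visit3 = 2, visit4 = 2)
  expect_equal(as.numeric(computeOutcome(flat, "average_difference")), 0)
  expect_equal(as.numeric(computeOutcome(flat, "single_difference")), 0)
  gap <- visits; gap$visit3 <- NA
  expect_error(computeOutcome(gap, "average_difference"), "impute")
})

test_that("null model recovers variance parameters", {
  ## unrelated data: tau ~ 0, sigma2 ~ sample variance
  withr::with_seed(9, {
    n <- 500
    phi <- diag(n); dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
    y <- rnorm(n, sd = 1.3)
    fit <- fitNullModel(setNames(y, rownames(phi)), phi)
    expect_lt(fit$tau, 0.15)
    expect_equal(fit$sigma2 + fit$tau, var(y) * (n - 1) / n, tolerance = 0.05)
  })

  ## family data: (tau, sigma2) = (1, 1) recovered within 3 MC SE
  ped <- simulatePedigrees(200, "nuclear_4")
  phi <- computePhi(ped)
  vcTrue <- VarianceComponents(sigmaA = diag(c(1, 0)),
                               sigmaE = diag(c(1, 0)) + 1e-8 * diag(2))
  est <- withr::with_seed(10, replicate(30, {
    y <- phenoValues(simulatePhenotypes(phi, vcTrue))[, 1]
    f <- fitNullModel(setNames(y, rownames(phi)), phi)
    c(f$tau, f$sigma2)
  }))
  for (k in 1:2) {
    se <- sd(est[k, ]) / sqrt(ncol(est))
    expect_lt(abs(mean(est[k, ]) - 1), 3 * se + 0.02)
  }

  expect_error(fitNullModel(rep(1, 10), diag(10)), "constant")
})

test_that("score test reduces to the classical regression score test when phi = I", {
  withr::with_seed(12, {
    n <- 300
    phi <- diag(n); dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
    y <- rnorm(n)
    null <- fitNullModel(setNames(y, rownames(phi)), phi)
    for (i in 1:5) {
      g <- rbinom(n, 2, runif(1, 0.1, 0.5))
      res <- scoreTest(null, g)
      statOracle <- n * cor(g, y)^2          # score statistic of OLS slope
      expect_equal(res$stat, statOracle, tolerance = 1e-6)
      expect_equal(res$p, pchisq(statOracle, 1, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  })
})

test_that("degenerate genotypes are handled: monomorphic flag, extreme association", {
  withr::with_seed(13, {
    n <- 200
    phi <- diag(n); dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
    y <- rnorm(n)
    null <- fitNullModel(setNames(y, rownames(phi)), phi)
    res <- scoreTest(null, rep(2, n))
    expect_true(res$monomorphic)
    expect_true(is.na(res$p))

    ## outcome equal to (scaled) genotype: essentially perfect association
    g <- rbinom(n, 2, 0.4)
    null2 <- fitNullModel(setNames(g / 2 + rnorm(n, sd = 1e-4), rownames(phi)),
                          phi)
    res2 <- scoreTest(null2, g)
    expect_true(is.finite(res2$stat))
    expect_lt(res2$p, 1e-40)

    expect_error(scoreTest(null, rep(3, n)), "0, 2")
  })
})

test_that("ignoring the pedigree random effect inflates type-I error on families", {
  ped <- simulatePedigrees(120, "nuclear_4")
  phi <- computePhi(ped)
  n <- nrow(phi)
  vcTrue <- VarianceComponents(sigmaA = diag(c(1.5, 0)),
                               sigmaE = diag(c(0.5, 0)) + 1e-8 * diag(2))
  phiI <- diag(n); dimnames(phiI) <- dimnames(phi)
  withr::with_seed(123, {
    pW <- c(); pI <- c()
    G <- geneDrop(ped, maf = 0.3, nVariants = 400)
    for (r in 1:25) {
      y <- setNames(phenoValues(simulatePhenotypes(phi, vcTrue))[, 1],
                    rownames(phi))
      pW <- c(pW, scanGenotypes(fitNullModel(y, phi), G)$p)
      pI <- c(pI, scanGenotypes(fitNullModel(y, phiI), G)$p)
    }
    rateW <- mean(pW < 0.05); rateI <- mean(pI < 0.05)
    expect_gt(rateI, rateW)
    ## modeled analysis is calibrated, unmodeled is clearly inflated
    bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / length(pW))
    expect_lt(rateW, 0.05 + 0.01)
    expect_gt(rateI, bound)
  })
})

test_that("null p-values are calibrated at 0.05 and 1e-3 over 1e5 tests", {
  ## unrelated null datasets; independent SNPs make tests approximately
  ## independent, so the pooled rate obeys the binomial law
  withr::with_seed(77, {
    n <- 300
    phi <- diag(n); dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
    p <- c()
    for (r in 1:50) {
      y <- setNames(rnorm(n), rownames(phi))
      null <- fitNullModel(y, phi)
      G <- matrix(rbinom(n * 2000, 2, 0.3), n, 2000)
      p <- c(p, scanGenotypes(null, G)$p)
    }
    for (alpha in c(0.05, 1e-3)) {
      rate <- mean(p < alpha)
      band <- 2.576 * sqrt(alpha * (1 - alpha) / length(p))
      expect_lt(abs(rate - alpha), band + 0.1 * alpha)
    }
  })
})

test_that("association results serialize to TSV", {
  withr::with_seed(1, {
    n <- 50
    phi <- diag(n); dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
    null <- fitNullModel(setNames(rnorm(n), rownames(phi)), phi)
    G <- matrix(rbinom(n * 3, 2, 0.3), n, 3,
                dimnames = list(rownames(phi), c("s1", "s2", "s3")))
    res <- scanGenotypes(null, G)
    tf <- withr::local_tempfile()
    writeAssociation(res, tf)
    back <- read.table(tf, header = TRUE, sep = "\t")
    expect_equal(back$snp, c("s1", "s2", "s3"))
    expect_equal(back$p, res$p, tolerance = 1e-12)
  })
})
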