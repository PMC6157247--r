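## Brute-force oracles and random-instance generators shared by the tests.
## These deliberately use dense linear algebra (solve/determinant on the full
## joint covariance) and never the package's block-decomposed code paths.

## Dense multivariate-normal log-density of the observed entries.
denseLoglikOracle <- function(vc, mu, panel, phi) {
  Sigma <- buildJointCovariance(vc, phi)
  y <- stackedY(panel)
  obs <- !is.na(y)
  muv <- stackedMu(mu, length(panelIds(panel)))
  S <- Sigma[obs, obs, drop = FALSE]
  r <- y[obs] - muv[obs]
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  as.numeric(-0.5 * (sum(obs) * log(2 * pi) + ld + t(r) %*% solve(S, r)))
}

## Conditional mean of missing entries by direct inversion of the full
## observed-block covariance.
bruteConditionalOracle <- function(panel, mu, Sigma) {
  y <- stackedY(panel)
  muv <- stackedMu(mu, length(panelIds(panel)))
  m <- which(is.na(y)); o <- which(!is.na(y))
  as.numeric(muv[m] +
    Sigma[m, o, drop = FALSE] %*% solve(Sigma[o, o, drop = FALSE],
                                        y[o] - muv[o]))
}

## Random multi-generation pedigree without inbreeding (6..maxMembers
## members): grows by either marrying a new founder into the family or
## adding a child to an existing couple.
randomPedigree <- function(maxMembers = 20, seed = NULL) {
  gen <- function() {
    target <- sample(6:maxMembers, 1)
    fam <- "FAM1"
    id <- c("p1", "p2"); dad <- c(NA, NA); mom <- c(NA, NA); sex <- c(1L, 2L)
    couples <- list(c("p1", "p2"))
    k <- 2L
    while (k < target) {
      k <- k + 1L
      nid <- paste0("p", k)
      if (runif(1) < 0.4 || length(couples) == 0L) {
        ## new founder marries a random existing individual of opposite sex
        spouse <- sample(id, 1)
        ssex <- sex[match(spouse, id)]
        id <- c(id, nid); dad <- c(dad, NA); mom <- c(mom, NA)
        sex <- c(sex, 3L - ssex)
        couples[[length(couples) + 1L]] <-
          if (ssex == 1L) c(spouse, nid) else c(nid, spouse)
      } else {
        cp <- couples[[sample(length(couples), 1)]]
        id <- c(id, nid); dad <- c(dad, cp[1]); mom <- c(mom, cp[2])
        sex <- c(sex, sample(1:2, 1))
      }
    }
    Pedigree(famID = fam, id = id, dadID = dad, momID = mom, sex = sex)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

## Random PSD 2x2 covariance matrix with variances in [0.3, 2].
random2x2 <- function() {
  v <- runif(2, 0.3, 2)
  r <- runif(1, -0.9, 0.9)
  matrix(c(v[1], r * sqrt(v[1] * v[2]), r * sqrt(v[1] * v[2]), v[2]), 2, 2)
}

## Random small panel + phi + generating components, with a random mask
## leaving at least one observed entry.
randomInstance <- function(maxFamilies = 3, maxMissing = NULL) {
  nf <- sample(seq_len(maxFamilies), 1)
  tpl <- sample(c("sib_pair", "nuclear_4", "singleton"), 1)
  ped <- simulatePedigrees(nf, tpl)
  phi <- computePhi(ped, onlyPhenotyped = TRUE)
  vc <- VarianceComponents(sigmaA = random2x2(), sigmaE = random2x2())
  mu <- runif(2, -1, 1)
  panel <- simulatePhenotypes(phi, vc, mu = mu)
  v <- phenoValues(panel)
  nMiss <- if (is.null(maxMissing)) sample.int(length(v) - 1L, 1) else
    sample.int(maxMissing, 1)
  v[sample(length(v), min(nMiss, length(v) - 1L))] <- NA
  list(panel = PhenotypePanel(panelIds(panel), v), phi = phi, vc = vc,
       mu = mu)
}
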