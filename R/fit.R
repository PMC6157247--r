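## Maximum-likelihood fitting of the bivariate polygenic model.

.thetaToSigma <- function(theta3) {
  ## log-Cholesky parameterization of one 2x2 PSD matrix:
  ## L = [exp(t1) 0; t2 exp(t3)], Sigma = L L'
  L <- matrix(c(exp(theta3[1L]), theta3[2L], 0, exp(theta3[3L])), 2, 2)
  tcrossprod(L)
}

.sigmaToTheta <- function(S) {
  ## inverse of .thetaToSigma for positive-definite S
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

.momentStart <- function(panel) {
  ## covariance of the two phenotypes from complete pairs, floored away from
  ## singularity, split 40/60 into genetic and environmental parts
  v <- phenoValues(panel)
  cc <- complete.cases(v)
  S <- if (sum(cc) >= 3L) cov(v[cc, , drop = FALSE]) else diag(2)
  vfloor <- 1e-3 * max(diag(S), 1e-6)
  diag(S) <- pmax(diag(S), vfloor)
  rmax <- 0.95 * sqrt(S[1, 1] * S[2, 2])
  S[1, 2] <- S[2, 1] <- sign(S[1, 2]) * min(abs(S[1, 2]), rmax)
  list(sigmaA = 0.4 * S, sigmaE = 0.6 * S)
}

#' Fit the bivariate polygenic model by maximum likelihood
#'
#' Estimates the 2 x 2 additive-genetic and environmental covariance matrices
#' (sigmaA, sigmaE) of the bivariate polygenic model by maximizing the
#' observed-data log-likelihood (see \code{\link{polygenicLoglik}}). The
#' per-phenotype means are the observed means, estimated once and held fixed.
#' Positive semidefiniteness is enforced through a log-Cholesky
#' parameterization of each matrix (6 free parameters); optimization is
#' quasi-Newton (L-BFGS-B) from a moment-based start plus \code{nRestarts}
#' randomly perturbed starts, keeping the best converged point.
#'
#' When phi is the identity (no related individuals) only the total
#' covariance sigmaA + sigmaE is identified; a warning is issued and the
#' split between the two matrices is arbitrary (downstream imputation depends
#' only on their total in that case).
#'
#' @param panel a \linkS4class{PhenotypePanel}; both phenotypes must have at
#'   least one observed value.
#' @param phi relationship matrix aligned with the panel ids.
#' @param nRestarts number of random restarts in addition to the moment start.
#' @param seed seed for the (deterministic) restart perturbations.
#' @param pgtol projected-gradient tolerance passed to the optimizer.
#' @param maxit maximum iterations per start.
#' @return a \linkS4class{VarianceComponents} with the converged
#'   log-likelihood and the number of observed values.
#' @export
fitBivariatePolygenic <- function(panel, phi, nRestarts = 5L, seed = 1L,
                                  pgtol = 1e-6, maxit = 500L) {
  mu <- observedMeans(panel)
  decomp <- .panelDecomposition(panel, phi)
  offdiag <- phi; diag(offdiag) <- 0
  if (max(abs(offdiag)) < 1e-12)
    warning("phi is the identity: only sigmaA + sigmaE is identified")

  nll <- function(theta) {
    ll <- .loglikDecomp(.thetaToSigma(theta[1:3]), .thetaToSigma(theta[4:6]),
                        mu, decomp)
    if (!is.finite(ll)) 1e10 else -ll
  }

  ms <- .momentStart(panel)
  theta0 <- c(.sigmaToTheta(ms$sigmaA), .sigmaToTheta(ms$sigmaE))
  starts <- list(theta0)
  if (nRestarts > 0L) {
    pert <- .withSeed(seed,
                      matrix(rnorm(6L * nRestarts, sd = 0.5), nrow = nRestarts))
    for (r in seq_len(nRestarts)) starts[[r + 1L]] <- theta0 + pert[r, ]
  }

  lower <- rep(c(-12, -50, -12), 2L)
  upper <- rep(c(12, 50, 12), 2L)
  best <- NULL
  diagnostics <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s, lower), upper), nll, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(pgtol = pgtol, maxit = maxit)),
      error = function(e) NULL)
    if (is.null(fit)) { diagnostics <- c(diagnostics, "optimizer error"); next }
    if (fit$value >= 1e10) { diagnostics <- c(diagnostics, "non-finite likelihood"); next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("bivariate polygenic fit failed on all starts: ",
         paste(unique(diagnostics), collapse = "; "))
  VarianceComponents(sigmaA = .thetaToSigma(best$par[1:3]),
                     sigmaE = .thetaToSigma(best$par[4:6]),
                     loglik = -best$value, nObs = decomp$nObs)
}

#' Serialize variance components to a flat key-value file
#'
#' Writes \code{key<TAB>value} lines (sigmaA.11, sigmaA.12, sigmaA.22,
#' sigmaE.11, sigmaE.12, sigmaE.22, loglik, n_obs); \code{readVarianceComponents}
#' reads them back.
#'
#' @param vc a \linkS4class{VarianceComponents}.
#' @param path file path.
#' @export
writeVarianceComponents <- function(vc, path) {
  a <- sigmaA(vc); e <- sigmaE(vc)
  kv <- c(sigmaA.11 = a[1, 1], sigmaA.12 = a[1, 2], sigmaA.22 = a[2, 2],
          sigmaE.11 = e[1, 1], sigmaE.12 = e[1, 2], sigmaE.22 = e[2, 2],
          loglik = fittedLoglik(vc), n_obs = vc@nObs)
  writeLines(sprintf("%s\t%.17g", names(kv), kv), path)
  invisible(path)
}

#' @rdname writeVarianceComponents
#' @export
readVarianceComponents <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  kv <- setNames(tab[[2L]], tab[[1L]])
  VarianceComponents(
    sigmaA = matrix(c(kv[["sigmaA.11"]], kv[["sigmaA.12"]],
                      kv[["sigmaA.12"]], kv[["sigmaA.22"]]), 2, 2),
    sigmaE = matrix(c(kv[["sigmaE.11"]], kv[["sigmaE.12"]],
                      kv[["sigmaE.12"]], kv[["sigmaE.22"]]), 2, 2),
    loglik = kv[["loglik"]], nObs = as.integer(kv[["n_obs"]]))
}
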