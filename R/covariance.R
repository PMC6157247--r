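#' Joint covariance of the stacked phenotype vector
#'
#' Builds the 2n x 2n covariance
#' \code{Sigma = sigmaA \%x\% phi + sigmaE \%x\% I} of the phenotype-major
#' stacked vector Y: the (k, l) phenotype block equals
#' \code{sigmaA[k, l] * phi + sigmaE[k, l] * I}. Additive-genetic covariance
#' is shared between relatives in proportion to phi; environmental covariance
#' acts only within an individual.
#'
#' @param vc a \linkS4class{VarianceComponents} object.
#' @param phi n x n relationship matrix.
#' @return 2n x 2n symmetric matrix; row/column names are
#'   \code{p<k>.<id>} following the stacked ordering.
#' @export
buildJointCovariance <- function(vc, phi) {
  n <- nrow(phi)
  if (n != ncol(phi)) stop("phi must be square")
  Sigma <- kronecker(sigmaA(vc), phi) + kronecker(sigmaE(vc), diag(n))
  ids <- rownames(phi)
  if (!is.null(ids)) {
    nm <- c(paste0("p1.", ids), paste0("p2.", ids))
    dimnames(Sigma) <- list(nm, nm)
  }
  Sigma
}

#' Observed per-phenotype means
#'
#' The mean vector of the model has one scalar per phenotype, each element of
#' a phenotype block being the arithmetic mean of that phenotype's observed
#' values; missing entries are excluded. The mean is estimated once and held
#' fixed during variance-component optimization.
#'
#' @param panel a \linkS4class{PhenotypePanel}.
#' @return named numeric(2), \code{c(mu1, mu2)}.
#' @export
observedMeans <- function(panel) {
  v <- phenoValues(panel)
  nObs <- colSums(!is.na(v))
  if (any(nObs == 0L))
    stop("phenotype ", which(nObs == 0L)[1L], " has no observed values")
  setNames(colMeans(v, na.rm = TRUE), c("mu1", "mu2"))
}

#' Expand per-phenotype means to the stacked length-2n vector
#'
#' @param mu numeric(2) per-phenotype means.
#' @param n number of individuals.
#' @export
stackedMu <- function(mu, n) rep(as.numeric(mu), each = n)

## ---------------------------------------------------------------------------
## Observed-data likelihood, decomposed over independent family blocks
## ---------------------------------------------------------------------------

## Sigma is block-diagonal across the connected components of phi (after
## reordering individuals by component), so the observed-data log-likelihood
## is a sum of small multivariate-normal densities, one per component.
## Components sharing the same (phi block, missingness pattern) signature are
## further grouped so their Cholesky factor is computed once and quadratic
## forms are evaluated as a single matrix solve. On template-replicated
## simulated pedigrees this reduces a likelihood evaluation to a handful of
## small factorizations.
.panelDecomposition <- function(panel, phi) {
  v <- phenoValues(panel)
  n <- nrow(v)
  if (nrow(phi) != n) stop("phi and panel dimensions differ")
  if (!is.null(rownames(phi)) && !identical(rownames(phi), panelIds(panel)))
    stop("phi ids do not match panel ids")
  comp <- .phiComponents(phi)
  groups <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    k <- length(idx)
    phiB <- phi[idx, idx, drop = FALSE]
    obs <- !is.na(as.vector(v[idx, , drop = FALSE]))   # stacked, length 2k
    if (!any(obs)) next
    yObs <- as.vector(v[idx, , drop = FALSE])[obs]
    sig <- paste(k, paste(signif(phiB, 12), collapse = ","),
                 paste(as.integer(obs), collapse = ""), sep = "|")
    if (is.null(groups[[sig]])) {
      groups[[sig]] <- list(phiB = phiB, obs = obs, k = k,
                            phenoIdx = rep(1:2, each = k)[obs],
                            Y = matrix(yObs, ncol = 1L))
    } else {
      groups[[sig]]$Y <- cbind(groups[[sig]]$Y, yObs)
    }
  }
  list(groups = groups,
       nObs = sum(!is.na(v)),
       n = n)
}

.loglikDecomp <- function(sigmaA, sigmaE, mu2, decomp) {
  ll <- 0
  log2pi <- log(2 * pi)
  for (g in decomp$groups) {
    Sigma <- kronecker(sigmaA, g$phiB) + kronecker(sigmaE, diag(g$k))
    Soo <- Sigma[g$obs, g$obs, drop = FALSE]
    U <- tryCatch(chol(Soo), error = function(e) NULL)
    if (is.null(U)) return(-Inf)
    R <- g$Y - mu2[g$phenoIdx]
    z <- backsolve(U, R, transpose = TRUE)
    m <- nrow(Soo)
    ll <- ll - 0.5 * (ncol(R) * (m * log2pi + .logdetFromChol(U)) + sum(z * z))
  }
  ll
}

#' Observed-data log-likelihood of the bivariate polygenic model
#'
#' Evaluates the multivariate normal log-density of the observed phenotype
#' entries Y_o under mean \code{stackedMu(mu, n)} restricted to observed
#' positions and covariance \code{Sigma_oo}, the observed-row/column
#' restriction of \code{sigmaA \%x\% phi + sigmaE \%x\% I}. Only observed
#' entries contribute (observed-data likelihood; no EM). The computation is
#' decomposed over the independent family blocks of phi.
#'
#' @param vc a \linkS4class{VarianceComponents} object.
#' @param mu numeric(2) per-phenotype means (see \code{\link{observedMeans}}).
#' @param panel a \linkS4class{PhenotypePanel}.
#' @param phi relationship matrix aligned with the panel ids.
#' @return the log-likelihood; \code{-Inf} when the restricted covariance is
#'   not positive definite (a rejected point during optimization).
#' @export
polygenicLoglik <- function(vc, mu, panel, phi) {
  decomp <- .panelDecomposition(panel, phi)
  .loglikDecomp(sigmaA(vc), sigmaE(vc), as.numeric(mu), decomp)
}
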