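## Conditional multivariate-normal imputation of missing phenotype entries.

#' Partition the stacked phenotype problem into missing/observed blocks
#'
#' Splits the stacked mean vector and joint covariance along the missingness
#' mask of the panel: positions follow stacked-Y (phenotype-major) order
#' within both the missing and observed blocks, so reassembling the four
#' covariance blocks reproduces Sigma exactly and
#' \code{Sigma_om = t(Sigma_mo)}.
#'
#' @param panel a \linkS4class{PhenotypePanel}.
#' @param mu numeric(2) per-phenotype means.
#' @param Sigma 2n x 2n joint covariance (see
#'   \code{\link{buildJointCovariance}}).
#' @return list with \code{muM}, \code{muO}, \code{SigmaMM}, \code{SigmaMO},
#'   \code{SigmaOO}, \code{yO} and the stacked index vectors \code{missIdx},
#'   \code{obsIdx}.
#' @export
partitionBlocks <- function(panel, mu, Sigma) {
  y <- stackedY(panel)
  n <- length(panelIds(panel))
  if (!identical(dim(Sigma), c(2L * n, 2L * n)))
    stop("Sigma must be 2n x 2n for the panel's n")
  muVec <- stackedMu(mu, n)
  missIdx <- which(is.na(y))
  obsIdx <- which(!is.na(y))
  if (length(obsIdx) == 0L) stop("panel has no observed entries")
  list(muM = muVec[missIdx], muO = muVec[obsIdx],
       SigmaMM = Sigma[missIdx, missIdx, drop = FALSE],
       SigmaMO = Sigma[missIdx, obsIdx, drop = FALSE],
       SigmaOO = Sigma[obsIdx, obsIdx, drop = FALSE],
       yO = y[obsIdx], missIdx = missIdx, obsIdx = obsIdx)
}

#' Conditional mean of missing entries given observed entries
#'
#' Computes \code{E(Y_m | Y_o) = mu_m + Sigma_mo Sigma_oo^{-1} (Y_o - mu_o)},
#' the best predictor of the missing block of a multivariate normal vector.
#' The linear solve uses a symmetric (Cholesky) factorization of Sigma_oo,
#' never an explicit inverse; if the factorization fails, a diagonal jitter
#' of \code{1e-8 * mean(diag(Sigma_oo))} is added and escalated tenfold for
#' at most 3 attempts.
#'
#' @param muM,muO mean sub-vectors of the missing/observed blocks.
#' @param SigmaMO cross-covariance block (missing x observed).
#' @param SigmaOO observed-block covariance.
#' @param yO observed values.
#' @param names optional labels (e.g. individual ids) used in the error
#'   message when Sigma_oo stays singular.
#' @return numeric vector of conditional expectations, one per missing entry,
#'   in block order.
#' @export
conditionalMean <- function(muM, muO, SigmaMO, SigmaOO, yO, names = NULL) {
  if (length(muM) == 0L) return(numeric(0))
  if (length(yO) == 0L) return(as.numeric(muM))
  U <- .cholJitter(SigmaOO)
  if (is.null(U)) {
    who <- if (is.null(names)) "" else
      paste0(" (observed entries: ", paste(names, collapse = ", "), ")")
    stop("Sigma_oo is numerically singular after jitter escalation", who)
  }
  as.numeric(muM + SigmaMO %*% .cholSolve(U, yO - muO))
}

#' Conditional covariance of missing entries given observed entries
#'
#' \code{Sigma_mm - Sigma_mo Sigma_oo^{-1} Sigma_om}; its diagonal is the
#' per-entry uncertainty of the conditional-mean imputation and is reported
#' as a diagnostic alongside imputed panels.
#'
#' @inheritParams conditionalMean
#' @param SigmaMM missing-block covariance.
#' @export
conditionalVariance <- function(SigmaMM, SigmaMO, SigmaOO) {
  if (nrow(SigmaMM) == 0L) return(SigmaMM)
  if (nrow(SigmaOO) == 0L) return(SigmaMM)
  U <- .cholJitter(SigmaOO)
  if (is.null(U)) stop("Sigma_oo is numerically singular after jitter escalation")
  SigmaMM - SigmaMO %*% .cholSolve(U, t(SigmaMO))
}

#' Impute all missing panel entries by the conditional mean
#'
#' Completes a bivariate phenotype panel: every missing entry is replaced by
#' its conditional expectation given all observed entries of the panel, under
#' the joint covariance \code{sigmaA \%x\% phi + sigmaE \%x\% I} and the
#' observed per-phenotype means. Observed entries are returned untouched.
#' Because the joint covariance is block-diagonal across the family
#' components of phi, conditioning is performed family by family, which is
#' exactly equivalent to conditioning the full joint distribution.
#'
#' This is single deterministic conditional-mean imputation (no draws from
#' the conditional distribution); the conditional variance of each imputed
#' entry is recorded as a diagnostic but not propagated downstream.
#'
#' @param panel a \linkS4class{PhenotypePanel}.
#' @param vc fitted (or supplied) \linkS4class{VarianceComponents}.
#' @param phi relationship matrix aligned with the panel ids.
#' @param mu optional numeric(2) means; defaults to
#'   \code{\link{observedMeans}} of the panel.
#' @return an \linkS4class{ImputedPanel}.
#' @export
imputePanel <- function(panel, vc, phi, mu = NULL) {
  v <- phenoValues(panel)
  n <- nrow(v)
  if (nrow(phi) != n) stop("phi and panel dimensions differ")
  if (is.null(mu)) mu <- observedMeans(panel)
  prov <- matrix("observed", n, 2L, dimnames = dimnames(v))
  cvar <- matrix(NA_real_, n, 2L, dimnames = dimnames(v))
  out <- v
  sA <- sigmaA(vc); sE <- sigmaE(vc)
  comp <- .phiComponents(phi)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    vb <- v[idx, , drop = FALSE]
    if (!anyNA(vb)) next
    k <- length(idx)
    Sigma <- kronecker(sA, phi[idx, idx, drop = FALSE]) +
      kronecker(sE, diag(k))
    yb <- as.vector(vb)
    muVec <- rep(as.numeric(mu), each = k)
    mIdx <- which(is.na(yb)); oIdx <- which(!is.na(yb))
    SigmaMO <- Sigma[mIdx, oIdx, drop = FALSE]
    SigmaOO <- Sigma[oIdx, oIdx, drop = FALSE]
    ids <- panelIds(panel)[idx]
    obsNames <- paste0("p", rep(1:2, each = k)[oIdx], ".", ids[rep_len(seq_len(k), 2L * k)[oIdx]])
    imp <- conditionalMean(muVec[mIdx], muVec[oIdx], SigmaMO, SigmaOO,
                           yb[oIdx], names = obsNames)
    cv <- conditionalVariance(Sigma[mIdx, mIdx, drop = FALSE], SigmaMO, SigmaOO)
    yb[mIdx] <- imp
    filled <- matrix(yb, k, 2L)
    out[idx, ] <- filled
    missMat <- is.na(vb)
    prov[idx, ][missMat] <- "mvn_imputed"
    cvar[idx, ][missMat] <- diag(cv)
  }
  new("ImputedPanel", ids = panelIds(panel),
      values = out, provenance = prov, condVar = cvar)
}

#' Carry-over fill of the pre-treatment visits
#'
#' For four-visit tables where the first two visits measure the same
#' pre-treatment phenotype, a missing visit-1 value is copied from the
#' observed visit-2 value and vice versa. A sample missing both visit 1 and
#' visit 2 violates the rule's precondition and raises an error.
#'
#' @param visits data.frame with columns \code{id}, \code{visit1} ..
#'   \code{visit4} (\code{NA} = missing).
#' @return list with the filled \code{visits} data.frame and a
#'   \code{provenance} character matrix (columns visit1..visit4) marking
#'   carried-over entries as \code{"carryover_filled"}.
#' @export
carryoverFill <- function(visits) {
  need <- c("id", paste0("visit", 1:4))
  if (!all(need %in% names(visits)))
    stop("visits must have columns ", paste(need, collapse = ", "))
  both <- is.na(visits$visit1) & is.na(visits$visit2)
  if (any(both))
    stop("samples missing both visit 1 and visit 2 cannot be carry-over ",
         "filled: ", paste(visits$id[both], collapse = ", "))
  prov <- matrix("observed", nrow(visits), 4L,
                 dimnames = list(visits$id, paste0("visit", 1:4)))
  g1 <- is.na(visits$visit1)
  g2 <- is.na(visits$visit2)
  visits$visit1[g1] <- visits$visit2[g1]
  visits$visit2[g2] <- visits$visit1[g2]
  prov[g1, "visit1"] <- "carryover_filled"
  prov[g2, "visit2"] <- "carryover_filled"
  prov[is.na(as.matrix(visits[paste0("visit", 1:4)]))] <- NA_character_
  list(visits = visits, provenance = prov)
}
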