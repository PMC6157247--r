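## Evaluation drivers: type-I error, power, imputation-accuracy MSE,
## each comparing analyses on incomplete versus imputed data.

#' Impute the missing first post-treatment visit of a four-visit table
#'
#' The end-to-end imputation pipeline used by the evaluation drivers:
#' deterministic carry-over fill of pre-treatment gaps first, then a
#' bivariate panel is formed from the pre-treatment average (phenotype 1)
#' and visit 3 (phenotype 2), the bivariate polygenic model is fitted on it
#' by maximum likelihood, and missing visit-3 values are replaced by their
#' conditional means.
#'
#' @param visits four-visit data.frame (visit 3 may have gaps; visits 1/2
#'   gaps are carry-over filled, visit 4 must be complete).
#' @param phi relationship matrix aligned with \code{visits$id}.
#' @param fitRestarts random restarts for the variance-component fit.
#' @return list with the completed \code{visits}, the fitted \code{vc} and
#'   the \linkS4class{ImputedPanel} \code{panel}.
#' @export
imputeVisit3 <- function(visits, phi, fitRestarts = 1L) {
  if (anyNA(visits$visit1) || anyNA(visits$visit2))
    visits <- carryoverFill(visits)$visits
  panel <- PhenotypePanel(ids = visits$id,
                          pheno1 = (visits$visit1 + visits$visit2) / 2,
                          pheno2 = visits$visit3,
                          phenoNames = c("preAvg", "visit3"))
  vc <- fitBivariatePolygenic(panel, phi, nRestarts = fitRestarts)
  imp <- imputePanel(panel, vc, phi)
  visits$visit3 <- phenoValues(imp)[, 2L]
  list(visits = visits, vc = vc, panel = imp)
}

.binomMcse <- function(p, n) sqrt(pmax(p * (1 - p), 0) / n)

.evalSummary <- function(design, estimates, perReplicate, nReplicates, seed) {
  new("EvaluationSummary", design = design, estimates = estimates,
      perReplicate = perReplicate, nReplicates = as.integer(nReplicates),
      seed = as.integer(seed))
}

#' Type-I error evaluation on synthetic null SNPs
#'
#' For each replicate, phenotypes are re-simulated, visit-3 missingness is
#' applied, and every null SNP is score-tested against both outcomes on two
#' datasets: \emph{incomplete} (samples with a missing post-treatment visit
#' removed) and \emph{imputed} (visit 3 completed by
#' \code{\link{imputeVisit3}}, with variance components re-estimated within
#' the replicate). Rejection fractions are pooled over replicates per
#' (dataset, outcome, alpha) cell.
#'
#' @param config a \code{\link{simulationConfig}} with \code{causal = NULL}
#'   and \code{nNullSnps > 0}.
#' @param alphas nominal significance levels.
#' @param replicates number of phenotype replicates (defaults to the config).
#' @param seed integer seed driving all randomness.
#' @param fitRestarts restarts for the per-replicate variance-component fit.
#' @return an \linkS4class{EvaluationSummary} (design \code{"type1"}).
#' @export
runType1 <- function(config, alphas = c(0.05, 1e-3, 1e-4),
                     replicates = config$nReplicates, seed = 1L,
                     fitRestarts = 1L) {
  if (!is.null(config$causal) && nrow(config$causal) > 0L)
    stop("type-I error evaluation requires a config with only null SNPs ",
         "(set causal = NULL)")
  if (config$nNullSnps < 1L) stop("config must specify null SNPs")
  seeds <- .childSeeds(seed, replicates + 1L)
  sc <- .studyScaffold(config, seed = seeds[replicates + 1L])
  egFull <- eigen((sc$phi + t(sc$phi)) / 2, symmetric = TRUE)
  arms <- c("incomplete", "imputed")
  outcomes <- c("average_difference", "single_difference")
  counts <- array(0, dim = c(2L, 2L, length(alphas)),
                  dimnames = list(arms, outcomes, paste0("a", alphas)))
  nTests <- array(0, dim = c(2L, 2L, length(alphas)),
                  dimnames = dimnames(counts))
  perRep <- list()
  for (r in seq_len(replicates)) {
    rseeds <- .childSeeds(seeds[r], 2L)
    rep1 <- .simulateReplicate(sc, seed = rseeds[1L])
    vm <- maskVisit(rep1$visits, "visit3", config$missingFraction,
                    seed = rseeds[2L])
    keep <- !is.na(vm$visit3) & !is.na(vm$visit4)
    datasets <- list(
      incomplete = list(visits = vm[keep, , drop = FALSE],
                        phi = sc$phi[keep, keep, drop = FALSE],
                        G = sc$G[keep, , drop = FALSE], eg = NULL),
      imputed = list(visits = suppressWarnings(
                       imputeVisit3(vm, sc$phi, fitRestarts))$visits,
                     phi = sc$phi, G = sc$G, eg = egFull))
    for (arm in arms) {
      ds <- datasets[[arm]]
      eg <- if (is.null(ds$eg)) eigen((ds$phi + t(ds$phi)) / 2,
                                      symmetric = TRUE) else ds$eg
      for (oc in outcomes) {
        y <- computeOutcome(ds$visits, oc)
        null <- fitNullModel(y, ds$phi, eigenPhi = eg)
        p <- scanGenotypes(null, ds$G)$p
        p <- p[!is.na(p)]
        for (a in seq_along(alphas)) {
          counts[arm, oc, a] <- counts[arm, oc, a] + sum(p < alphas[a])
          nTests[arm, oc, a] <- nTests[arm, oc, a] + length(p)
        }
        perRep[[length(perRep) + 1L]] <-
          data.frame(rep = r, arm = arm, outcome = oc,
                     rate05 = mean(p < alphas[1L]), nTests = length(p))
      }
    }
  }
  grid <- expand.grid(arm = arms, outcome = outcomes, alpha = alphas,
                      stringsAsFactors = FALSE)
  est <- cbind(grid,
               nTests = mapply(function(a, o, al)
                 nTests[a, o, paste0("a", al)],
                 grid$arm, grid$outcome, grid$alpha),
               rate = mapply(function(a, o, al)
                 counts[a, o, paste0("a", al)] / nTests[a, o, paste0("a", al)],
                 grid$arm, grid$outcome, grid$alpha))
  est$mcse <- .binomMcse(est$rate, est$nTests)
  rownames(est) <- NULL
  .evalSummary("type1", est, do.call(rbind, perRep), replicates, seed)
}

#' Power evaluation on causal SNPs
#'
#' Per replicate, causal SNPs are score-tested against both outcomes on the
#' incomplete and imputed datasets (as in \code{\link{runType1}}); power per
#' (SNP, dataset, outcome, alpha) is the rejection fraction across
#' replicates.
#'
#' @inheritParams runType1
#' @param config a \code{\link{simulationConfig}} with a non-empty causal
#'   table.
#' @param alphas significance levels (defaults to 0.01 and 1e-4).
#' @return an \linkS4class{EvaluationSummary} (design \code{"power"}).
#' @export
runPower <- function(config, alphas = c(0.01, 1e-4),
                     replicates = config$nReplicates, seed = 1L,
                     fitRestarts = 1L) {
  if (is.null(config$causal) || nrow(config$causal) == 0L)
    stop("power evaluation requires causal SNPs in the config")
  seeds <- .childSeeds(seed, replicates + 1L)
  sc <- .studyScaffold(config, seed = seeds[replicates + 1L])
  egFull <- eigen((sc$phi + t(sc$phi)) / 2, symmetric = TRUE)
  nCausal <- nrow(config$causal)
  causalCols <- seq_len(nCausal)
  arms <- c("incomplete", "imputed")
  outcomes <- c("average_difference", "single_difference")
  pvals <- array(NA_real_,
                 dim = c(replicates, nCausal, 2L, 2L),
                 dimnames = list(NULL, paste0("causal", causalCols),
                                 arms, outcomes))
  for (r in seq_len(replicates)) {
    rseeds <- .childSeeds(seeds[r], 2L)
    rep1 <- .simulateReplicate(sc, seed = rseeds[1L])
    vm <- maskVisit(rep1$visits, "visit3", config$missingFraction,
                    seed = rseeds[2L])
    keep <- !is.na(vm$visit3) & !is.na(vm$visit4)
    datasets <- list(
      incomplete = list(visits = vm[keep, , drop = FALSE],
                        phi = sc$phi[keep, keep, drop = FALSE],
                        G = sc$G[keep, causalCols, drop = FALSE], eg = NULL),
      imputed = list(visits = suppressWarnings(
                       imputeVisit3(vm, sc$phi, fitRestarts))$visits,
                     phi = sc$phi,
                     G = sc$G[, causalCols, drop = FALSE], eg = egFull))
    for (arm in arms) {
      ds <- datasets[[arm]]
      eg <- if (is.null(ds$eg)) eigen((ds$phi + t(ds$phi)) / 2,
                                      symmetric = TRUE) else ds$eg
      for (oc in outcomes) {
        y <- computeOutcome(ds$visits, oc)
        null <- fitNullModel(y, ds$phi, eigenPhi = eg)
        pvals[r, , arm, oc] <- scanGenotypes(null, ds$G)$p
      }
    }
  }
  grid <- expand.grid(snp = paste0("causal", causalCols), arm = arms,
                      outcome = outcomes, alpha = alphas,
                      stringsAsFactors = FALSE)
  grid$varExplained <- config$causal$varExplained[
    match(grid$snp, paste0("causal", causalCols))]
  grid$power <- mapply(function(s, a, o, al)
    mean(pvals[, s, a, o] < al, na.rm = TRUE),
    grid$snp, grid$arm, grid$outcome, grid$alpha)
  grid$mcse <- .binomMcse(grid$power, replicates)
  rownames(grid) <- NULL
  perRep <- data.frame(rep = rep(seq_len(replicates), nCausal),
                       snp = rep(paste0("causal", causalCols),
                                 each = replicates),
                       pImputedAvg = as.vector(pvals[, , "imputed",
                                                     "average_difference"]))
  .evalSummary("power", grid, perRep, replicates, seed)
}

#' Imputation-accuracy (MSE) evaluation
#'
#' Per replicate a complete four-visit dataset is simulated; a fraction of
#' visit-2 values is masked completely at random and imputed twice, once
#' from visit 1 (within-period correlation, by default 0.9) and once from
#' visit 4 (cross-period correlation, by default 0.8), re-estimating
#' variance components on each masked panel. The MSE over masked entries is
#' averaged across replicates for every (missing fraction, source)
#' combination; the same mask is used for both sources within a replicate.
#'
#' @inheritParams runType1
#' @param fractions missing fractions to sweep.
#' @return an \linkS4class{EvaluationSummary} (design \code{"mse"}) whose
#'   estimates carry the nominal source correlation per row.
#' @export
runMSE <- function(config, fractions = c(0.2, 0.5, 0.8),
                   replicates = config$nReplicates, seed = 1L,
                   fitRestarts = 1L) {
  stopifnot(all(fractions > 0 & fractions < 1))
  seeds <- .childSeeds(seed, replicates + 1L)
  confNoCausal <- config
  confNoCausal$causal <- NULL
  sc <- .studyScaffold(confNoCausal, seed = seeds[replicates + 1L])
  sources <- data.frame(source = c("visit1", "visit4"),
                        nominalCor = c(config$corPre, config$corCross),
                        stringsAsFactors = FALSE)
  mse <- array(NA_real_, dim = c(replicates, length(fractions), 2L),
               dimnames = list(NULL, paste0("f", fractions), sources$source))
  n <- nrow(sc$phi)
  for (r in seq_len(replicates)) {
    rseeds <- .childSeeds(seeds[r], 1L + length(fractions))
    rep1 <- .simulateReplicate(sc, seed = rseeds[1L])
    truth <- rep1$visits$visit2
    for (f in seq_along(fractions)) {
      idx <- .maskIndices(n, fractions[f], seed = rseeds[1L + f])
      if (length(idx) == 0L) stop("empty mask at fraction ", fractions[f])
      for (s in seq_len(nrow(sources))) {
        src <- rep1$visits[[sources$source[s]]]
        target <- truth
        target[idx] <- NA_real_
        panel <- PhenotypePanel(ids = rep1$visits$id, pheno1 = src,
                                pheno2 = target,
                                phenoNames = c("source", "visit2"))
        vc <- suppressWarnings(
          fitBivariatePolygenic(panel, sc$phi, nRestarts = fitRestarts))
        imp <- imputePanel(panel, vc, sc$phi)
        mse[r, f, s] <- mean((phenoValues(imp)[idx, 2L] - truth[idx])^2)
      }
    }
  }
  grid <- expand.grid(fraction = fractions, source = sources$source,
                      stringsAsFactors = FALSE)
  grid$nominalCor <- sources$nominalCor[match(grid$source, sources$source)]
  grid$mse <- mapply(function(f, s)
    mean(mse[, paste0("f", f), s]), grid$fraction, grid$source)
  grid$mcse <- mapply(function(f, s)
    sd(mse[, paste0("f", f), s]) / sqrt(replicates),
    grid$fraction, grid$source)
  rownames(grid) <- NULL
  perRep <- data.frame(rep = seq_len(replicates),
                       mseV1F1 = mse[, 1L, 1L], mseV4F1 = mse[, 1L, 2L])
  .evalSummary("mse", grid, perRep, replicates, seed)
}

#' Write an evaluation summary as TSV
#'
#' @param summary an \linkS4class{EvaluationSummary}.
#' @param path file path.
#' @export
writeEvaluation <- function(summary, path) {
  write.table(evalEstimates(summary), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
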