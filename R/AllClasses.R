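#' @import methods
#' @importFrom stats cor cov optim optimize pchisq rbinom rnorm runif sd var
#'   complete.cases setNames
#' @importFrom utils read.table write.table packageVersion
NULL

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of one or more families
#'
#' Holds family/individual/parent links for a set of (possibly multiple)
#' families. Missing parents are stored as \code{NA}; founders have both
#' parents missing. The \code{phenotyped} flag marks individuals that belong
#' to the study sample (simulated pedigrees may carry untyped connecting
#' parents).
#'
#' @slot members data.frame with columns \code{famID}, \code{id},
#'   \code{dadID}, \code{momID}, \code{sex}, \code{phenotyped}.
#' @export
setClass("Pedigree", representation(members = "data.frame"))

.pedigreeTopoOrder <- function(members) {
  ## Kahn-style ordering placing parents before children; NULL on a cycle or
  ## on a parent reference that cannot be resolved.
  n <- nrow(members)
  placed <- logical(n)
  ord <- integer(0)
  dad <- match(members$dadID, members$id)
  mom <- match(members$momID, members$id)
  dadMissing <- is.na(members$dadID)
  momMissing <- is.na(members$momID)
  if (any(!dadMissing & is.na(dad)) || any(!momMissing & is.na(mom)))
    return(NULL)
  parentReady <- function(idx, missing) {
    r <- missing
    j <- which(!missing)
    r[j] <- placed[idx[j]]
    r
  }
  repeat {
    ready <- which(!placed & parentReady(dad, dadMissing) &
                     parentReady(mom, momMissing))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) return(NULL)
  ord
}

setValidity("Pedigree", function(object) {
  m <- object@members
  need <- c("famID", "id", "dadID", "momID", "sex", "phenotyped")
  if (!all(need %in% names(m)))
    return(paste("members must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id))
    return("duplicated individual ids")
  for (col in c("dadID", "momID")) {
    ref <- m[[col]][!is.na(m[[col]])]
    if (!all(ref %in% m$id))
      return(sprintf("%s refers to individuals absent from the pedigree: %s",
                     col, paste(setdiff(ref, m$id), collapse = ", ")))
  }
  if (any(!is.na(m$dadID) & m$dadID == m$id) ||
      any(!is.na(m$momID) & m$momID == m$id))
    return("an individual lists itself as its own parent")
  if (is.null(.pedigreeTopoOrder(m)))
    return("pedigree graph contains a cycle (an individual is its own ancestor)")
  ## parents must be in the same family
  dad <- match(m$dadID, m$id)
  mom <- match(m$momID, m$id)
  if (any(m$famID[dad[!is.na(dad)]] != m$famID[!is.na(dad)]) ||
      any(m$famID[mom[!is.na(mom)]] != m$famID[!is.na(mom)]))
    return("parent links cross family boundaries")
  TRUE
})

#' Construct a Pedigree
#'
#' @param famID,id character vectors (recycled famID allowed).
#' @param dadID,momID parent ids; \code{NA} (or \code{"0"}) for missing.
#' @param sex optional sex codes (1 = male, 2 = female, NA unknown).
#' @param phenotyped logical, is the individual part of the study sample.
#' @return A \linkS4class{Pedigree}.
#' @export
Pedigree <- function(famID, id, dadID = NA_character_, momID = NA_character_,
                     sex = NA_integer_, phenotyped = TRUE) {
  canon <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == "0"] <- NA_character_
    x
  }
  m <- data.frame(famID = as.character(famID), id = as.character(id),
                  dadID = canon(dadID), momID = canon(momID),
                  sex = as.integer(sex),
                  phenotyped = as.logical(phenotyped),
                  stringsAsFactors = FALSE)
  new("Pedigree", members = m)
}

#' @describeIn Pedigree accessor for the member table
#' @param ped a Pedigree
#' @export
pedMembers <- function(ped) ped@members

#' @describeIn Pedigree ids of study (phenotyped) individuals
#' @export
studyIds <- function(ped) ped@members$id[ped@members$phenotyped]

#' @describeIn Pedigree number of individuals
#' @export
pedSize <- function(ped) nrow(ped@members)

#' @describeIn Pedigree logical: has both parents missing
#' @export
isFounder <- function(ped) is.na(ped@members$dadID) & is.na(ped@members$momID)

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat(sprintf("Pedigree: %d individuals in %d families (%d founders, %d phenotyped)\n",
              nrow(m), length(unique(m$famID)), sum(isFounder(object)),
              sum(m$phenotyped)))
})

## ---------------------------------------------------------------------------
## PhenotypePanel
## ---------------------------------------------------------------------------

#' Bivariate phenotype panel
#'
#' Stores two phenotypes measured (possibly with gaps) on n individuals.
#' Missing values are \code{NA}. The stacked phenotype vector Y of length 2n
#' used throughout the model is phenotype-major: all individuals for
#' phenotype 1, then all individuals for phenotype 2 (see
#' \code{\link{stackedY}}).
#'
#' @slot ids ordered individual identifiers (length n).
#' @slot values numeric n x 2 matrix, \code{NA} where missing.
#' @export
setClass("PhenotypePanel",
         representation(ids = "character", values = "matrix"))

setValidity("PhenotypePanel", function(object) {
  v <- object@values
  if (!is.numeric(v) || ncol(v) != 2L)
    return("values must be a numeric n x 2 matrix (bivariate panel)")
  if (nrow(v) != length(object@ids))
    return("length(ids) must equal nrow(values)")
  if (anyDuplicated(object@ids)) return("duplicated ids")
  if (any(!is.na(v) & !is.finite(v)))
    return("observed phenotype values must be finite")
  TRUE
})

#' Construct a PhenotypePanel
#'
#' @param ids individual identifiers.
#' @param values numeric n x 2 matrix; \code{NA} marks a missing
#'   measurement.
#' @param pheno1,pheno2 alternatively, the two phenotype vectors.
#' @param phenoNames length-2 column names.
#' @export
PhenotypePanel <- function(ids, values = NULL, pheno1 = NULL, pheno2 = NULL,
                           phenoNames = c("pheno1", "pheno2")) {
  if (is.null(values)) values <- cbind(pheno1, pheno2)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(ids), phenoNames)
  new("PhenotypePanel", ids = as.character(ids), values = values)
}

#' @describeIn PhenotypePanel the n x 2 value matrix
#' @param panel a PhenotypePanel
#' @export
phenoValues <- function(panel) panel@values

#' @describeIn PhenotypePanel ids accessor
#' @export
panelIds <- function(panel) panel@ids

#' @describeIn PhenotypePanel n x 2 logical missingness mask (TRUE = missing)
#' @export
missingMask <- function(panel) is.na(panel@values)

#' @describeIn PhenotypePanel stacked length-2n phenotype vector
#'   (phenotype-major: y_11..y_1n, y_21..y_2n), \code{NA} where missing
#' @export
stackedY <- function(panel) as.vector(panel@values)

setMethod("show", "PhenotypePanel", function(object) {
  mm <- missingMask(object)
  cat(sprintf("PhenotypePanel: %d individuals x 2 phenotypes (%s); %d/%d values missing\n",
              length(object@ids),
              paste(colnames(object@values), collapse = ", "),
              sum(mm), length(mm)))
})

## ---------------------------------------------------------------------------
## ImputedPanel
## ---------------------------------------------------------------------------

#' Completed phenotype panel with provenance
#'
#' A \linkS4class{PhenotypePanel} with every gap filled. \code{provenance}
#' records, per entry, whether the value was observed, imputed by the
#' conditional multivariate normal mean, or copied by the carry-over rule.
#' \code{condVar} holds the conditional variance of each imputed entry given
#' the observed data (a diagnostic; \code{NA} for observed entries).
#'
#' @slot provenance character n x 2 matrix with entries in
#'   \code{c("observed", "mvn_imputed", "carryover_filled")}.
#' @slot condVar numeric n x 2 matrix of conditional variances.
#' @export
setClass("ImputedPanel", contains = "PhenotypePanel",
         representation(provenance = "matrix", condVar = "matrix"))

setValidity("ImputedPanel", function(object) {
  if (anyNA(object@values)) return("imputed panel must have no missing values")
  if (!identical(dim(object@provenance), dim(object@values)))
    return("provenance must have the same shape as values")
  ok <- c("observed", "mvn_imputed", "carryover_filled")
  if (!all(object@provenance %in% ok))
    return(paste("provenance entries must be one of", paste(ok, collapse = ", ")))
  TRUE
})

#' @describeIn ImputedPanel provenance matrix accessor
#' @param panel an ImputedPanel
#' @export
provenance <- function(panel) panel@provenance

#' @describeIn ImputedPanel conditional-variance diagnostic accessor
#' @export
conditionalVarDiag <- function(panel) panel@condVar

setMethod("show", "ImputedPanel", function(object) {
  tab <- table(factor(object@provenance,
                      c("observed", "mvn_imputed", "carryover_filled")))
  cat(sprintf("ImputedPanel: %d individuals; %d observed, %d MVN-imputed, %d carried over\n",
              length(object@ids), tab[1L], tab[2L], tab[3L]))
})

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' Bivariate polygenic variance components
#'
#' The 2 x 2 additive-genetic covariance matrix Sigma_A (shared between
#' relatives in proportion to the relationship matrix phi) and the 2 x 2
#' environmental covariance matrix Sigma_E (independent across individuals).
#' The joint covariance of the stacked phenotype vector is
#' \code{Sigma_A \%x\% phi + Sigma_E \%x\% I}.
#'
#' @slot sigmaA,sigmaE symmetric positive semidefinite 2 x 2 matrices, in
#'   squared phenotype units.
#' @slot loglik converged observed-data log-likelihood (NA if not fitted).
#' @slot nObs number of observed phenotype values used in the fit.
#' @export
setClass("VarianceComponents",
         representation(sigmaA = "matrix", sigmaE = "matrix",
                        loglik = "numeric", nObs = "integer"))

.checkCov2 <- function(S, label) {
  if (!identical(dim(S), c(2L, 2L))) return(paste(label, "must be 2 x 2"))
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
    return(paste(label, "must be symmetric"))
  if (any(diag(S) < -1e-10)) return(paste(label, "has a negative variance"))
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * (1 + max(abs(S))))
    return(paste(label, "must be positive semidefinite"))
  TRUE
}

setValidity("VarianceComponents", function(object) {
  ok <- .checkCov2(object@sigmaA, "sigmaA")
  if (!isTRUE(ok)) return(ok)
  .checkCov2(object@sigmaE, "sigmaE")
})

#' Construct a VarianceComponents object
#'
#' @param sigmaA,sigmaE symmetric PSD 2 x 2 matrices.
#' @param loglik optional fitted log-likelihood.
#' @param nObs optional number of observed values.
#' @export
VarianceComponents <- function(sigmaA, sigmaE, loglik = NA_real_,
                               nObs = NA_integer_) {
  dimnames(sigmaA) <- dimnames(sigmaE) <- NULL
  new("VarianceComponents", sigmaA = (sigmaA + t(sigmaA)) / 2,
      sigmaE = (sigmaE + t(sigmaE)) / 2,
      loglik = as.numeric(loglik), nObs = as.integer(nObs))
}

#' @describeIn VarianceComponents additive-genetic covariance accessor
#' @param vc a VarianceComponents object
#' @export
sigmaA <- function(vc) vc@sigmaA

#' @describeIn VarianceComponents environmental covariance accessor
#' @export
sigmaE <- function(vc) vc@sigmaE

#' @describeIn VarianceComponents fitted log-likelihood
#' @export
fittedLoglik <- function(vc) vc@loglik

#' @describeIn VarianceComponents per-phenotype narrow-sense heritability
#'   sigma2_A / (sigma2_A + sigma2_E)
#' @export
heritability <- function(vc) {
  a <- diag(vc@sigmaA); e <- diag(vc@sigmaE)
  setNames(a / (a + e), c("pheno1", "pheno2"))
}

#' @describeIn VarianceComponents total phenotypic correlation implied by the
#'   components, (sigmaA12 + sigmaE12) / sqrt(prod of total variances)
#' @export
phenotypicCorrelation <- function(vc) {
  tot <- vc@sigmaA + vc@sigmaE
  tot[1, 2] / sqrt(tot[1, 1] * tot[2, 2])
}

setMethod("show", "VarianceComponents", function(object) {
  cat("Bivariate polygenic variance components\n")
  cat(sprintf("  sigmaA: [%.4g %.4g; %.4g %.4g]\n",
              object@sigmaA[1, 1], object@sigmaA[1, 2],
              object@sigmaA[2, 1], object@sigmaA[2, 2]))
  cat(sprintf("  sigmaE: [%.4g %.4g; %.4g %.4g]\n",
              object@sigmaE[1, 1], object@sigmaE[1, 2],
              object@sigmaE[2, 1], object@sigmaE[2, 2]))
  h2 <- heritability(object)
  cat(sprintf("  heritability: %.3f / %.3f;  phenotypic correlation: %.3f\n",
              h2[1], h2[2], phenotypicCorrelation(object)))
  if (!is.na(object@loglik))
    cat(sprintf("  log-likelihood: %.4f (n observed values = %d)\n",
                object@loglik, object@nObs))
})

## ---------------------------------------------------------------------------
## EvaluationSummary
## ---------------------------------------------------------------------------

#' Summary of a simulation evaluation
#'
#' Result container for the type-I error, power and imputation-accuracy
#' drivers. \code{estimates} carries one row per evaluated cell with its
#' Monte-Carlo standard error; \code{perReplicate} holds per-replicate
#' diagnostics.
#'
#' @slot design one of \code{"type1"}, \code{"power"}, \code{"mse"}.
#' @slot estimates data.frame of rates/MSEs with Monte-Carlo standard errors.
#' @slot perReplicate data.frame of per-replicate values (diagnostic).
#' @slot nReplicates number of simulation replicates.
#' @slot seed the seed the driver was run with.
#' @export
setClass("EvaluationSummary",
         representation(design = "character", estimates = "data.frame",
                        perReplicate = "data.frame", nReplicates = "integer",
                        seed = "integer"))

setValidity("EvaluationSummary", function(object) {
  if (!object@design %in% c("type1", "power", "mse"))
    return("design must be one of type1, power, mse")
  val <- intersect(c("rate", "power", "mse"), names(object@estimates))
  if (length(val) == 0L) return("estimates must carry a rate/power/mse column")
  if (!"mcse" %in% names(object@estimates))
    return("every estimate must carry a Monte-Carlo standard error (mcse)")
  v <- object@estimates[[val[1L]]]
  if (val[1L] != "mse" && any(v < 0 | v > 1))
    return("rates must lie in [0, 1]")
  TRUE
})

#' @describeIn EvaluationSummary estimates table accessor
#' @param x an EvaluationSummary
#' @export
evalEstimates <- function(x) x@estimates

setMethod("show", "EvaluationSummary", function(object) {
  cat(sprintf("EvaluationSummary (%s design, %d replicates, seed %d)\n",
              object@design, object@nReplicates, object@seed))
  print(object@estimates, row.names = FALSE, digits = 4)
})
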