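#' Read a pedigree file
#'
#' Parses whitespace- or tab-delimited pedigree files in the PLINK \code{.fam}
#' dialect (6 columns: FID IID PAT MAT SEX PHENO) or a generic PED dialect
#' (first 4-5 columns FID IID PAT MAT [SEX]; extra columns ignored). The
#' missing-parent code is \code{"0"}; ids are opaque strings.
#'
#' @param path file path.
#' @param dialect \code{"fam"} or \code{"ped"}.
#' @param onMissingParent what to do when a parent id is referenced but has no
#'   row of its own: \code{"fail"} (default) or \code{"create"}, which adds
#'   the parent as an untyped founder.
#' @return A \linkS4class{Pedigree}. Structural problems (cycles, dangling
#'   parent references under \code{"fail"}) raise errors.
#' @examples
#' tf <- tempfile()
#' writeLines(c("FAM1 C1 F1 M1 1 -9", "FAM1 F1 0 0 1 -9", "FAM1 M1 0 0 2 -9"), tf)
#' readPedigree(tf)
#' @export
readPedigree <- function(path, dialect = c("fam", "ped"),
                         onMissingParent = c("fail", "create")) {
  dialect <- match.arg(dialect)
  onMissingParent <- match.arg(onMissingParent)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("pedigree file must have at least 4 columns (FID IID PAT MAT)")
  fam <- tab[[1L]]; id <- tab[[2L]]; dad <- tab[[3L]]; mom <- tab[[4L]]
  sex <- if (ncol(tab) >= 5L) suppressWarnings(as.integer(tab[[5L]])) else NA_integer_
  dad[dad == "0"] <- NA_character_
  mom[mom == "0"] <- NA_character_
  if (onMissingParent == "create") {
    refs <- unique(c(dad, mom))
    refs <- refs[!is.na(refs) & !(refs %in% id)]
    if (length(refs)) {
      famOf <- vapply(refs, function(r) {
        fam[which(dad == r | mom == r)[1L]]
      }, character(1))
      fam <- c(fam, famOf); id <- c(id, refs)
      dad <- c(dad, rep(NA_character_, length(refs)))
      mom <- c(mom, rep(NA_character_, length(refs)))
      sex <- c(sex, rep(NA_integer_, length(refs)))
    }
  }
  Pedigree(famID = fam, id = id, dadID = dad, momID = mom, sex = sex,
           phenotyped = TRUE)
}

#' Write a pedigree as a PLINK .fam file
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param path output file.
#' @param pheno optional phenotype column (default \code{-9}).
#' @export
writeFam <- function(ped, path, pheno = -9) {
  m <- pedMembers(ped)
  out <- data.frame(m$famID, m$id,
                    ifelse(is.na(m$dadID), "0", m$dadID),
                    ifelse(is.na(m$momID), "0", m$momID),
                    ifelse(is.na(m$sex), 0L, m$sex), pheno)
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Relationship matrix from a pedigree
#'
#' Computes the pairwise genetic-correlation (numerator relationship) matrix
#' phi from pedigree structure: phi = 2 k, where k is the kinship coefficient
#' obtained by the standard recursion
#' \code{k(i, j) = (k(father(i), j) + k(mother(i), j)) / 2} for a non-founder
#' i (j not a descendant of i), with \code{k(i, i) = (1 + k(father(i),
#' mother(i))) / 2} and founders mutually unrelated. For non-inbred pedigrees
#' the diagonal is 1 and parent-offspring pairs are 0.5; inbreeding is
#' supported and inflates the diagonal above 1. Individuals in different
#' families are unrelated, so phi is block-diagonal across families.
#'
#' Note the convention: phi is \emph{twice} the kinship matrix (diagonal 1),
#' so that \code{sigmaA} in the bivariate polygenic model is directly the
#' additive-genetic covariance.
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param onlyPhenotyped restrict the returned matrix to study individuals
#'   (the principal submatrix, still a valid relationship matrix).
#' @return symmetric n x n matrix with id dimnames.
#' @export
computePhi <- function(ped, onlyPhenotyped = FALSE) {
  m <- pedMembers(ped)
  ord <- .pedigreeTopoOrder(m)
  if (is.null(ord)) stop("pedigree is not topologically orderable")
  m2 <- m[ord, , drop = FALSE]
  n <- nrow(m2)
  dad <- match(m2$dadID, m2$id)
  mom <- match(m2$momID, m2$id)
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- dad[i]; mi <- mom[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      kf <- if (is.na(di)) 0 else k[di, prev]
      km <- if (is.na(mi)) 0 else k[mi, prev]
      k[i, prev] <- k[prev, i] <- (kf + km) / 2
    }
    kpar <- if (is.na(di) || is.na(mi)) 0 else k[di, mi]
    k[i, i] <- (1 + kpar) / 2
  }
  phi <- 2 * k
  dimnames(phi) <- list(m2$id, m2$id)
  phi <- phi[m$id, m$id, drop = FALSE]   # restore input order
  if (onlyPhenotyped) {
    keep <- studyIds(ped)
    phi <- phi[keep, keep, drop = FALSE]
  }
  phi
}

#' Validate a relationship matrix
#'
#' Checks the invariants of a pedigree-derived relationship matrix: square,
#' symmetric, non-negative entries, diagonal >= 1 (1 for non-inbred
#' individuals), and positive semidefinite.
#'
#' @param phi matrix to check.
#' @param tol eigenvalue tolerance for the PSD check.
#' @return \code{TRUE} invisibly; stops with a message otherwise.
#' @export
validatePhi <- function(phi, tol = 1e-8) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi)) stop("phi must be square")
  if (max(abs(phi - t(phi))) > 1e-8) stop("phi must be symmetric")
  if (any(phi < -1e-12)) stop("phi entries must be non-negative")
  if (any(diag(phi) < 1 - 1e-8)) stop("phi diagonal must be >= 1")
  ev <- min(eigen((phi + t(phi)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol) stop("phi is not positive semidefinite (min eigenvalue ", ev, ")")
  invisible(TRUE)
}

#' Empirical relationship matrix from genotypes
#'
#' Estimates relatedness from a dosage matrix by the standardized-genotype
#' cross-product: with \code{z_vj = (g_vj - 2 p_v) / sqrt(2 p_v (1 - p_v))}
#' over polymorphic variants v, the estimate is \code{Z' Z / m}. The diagonal
#' is forced to 1 by construction, keeping the output on the same scale as
#' the pedigree-derived relationship matrix.
#'
#' @param dosages numeric matrix, variants in rows and samples in columns,
#'   additive 0/1/2 coding; column names are sample ids.
#' @param minMaf variants with minor-allele frequency at or below this are
#'   dropped before standardization.
#' @return symmetric n x n matrix with sample-id dimnames, diagonal 1.
#' @export
empiricalPhi <- function(dosages, minMaf = 0.01) {
  dosages <- as.matrix(dosages)
  p <- rowMeans(dosages) / 2
  keep <- pmin(p, 1 - p) > minMaf
  if (!any(keep))
    stop("no polymorphic variants (all monomorphic at minMaf = ", minMaf, ")")
  g <- dosages[keep, , drop = FALSE]
  p <- p[keep]
  z <- (g - 2 * p) / sqrt(2 * p * (1 - p))
  phi <- crossprod(z) / nrow(z)
  diag(phi) <- 1
  dimnames(phi) <- list(colnames(dosages), colnames(dosages))
  phi
}

#' Write / read a relationship matrix as TSV
#'
#' The format is a tab-separated matrix with a leading header row and a
#' first column both carrying the individual ids.
#'
#' @param phi relationship matrix with id dimnames.
#' @param path file path.
#' @export
writePhi <- function(phi, path) {
  df <- data.frame(id = rownames(phi), phi, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhi
#' @export
readPhi <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  phi <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(phi) <- list(ids, ids)
  phi
}
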