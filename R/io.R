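## Plain-text I/O for phenotypes and genotype dosages.

#' Read / write phenotype tables
#'
#' Tab-separated files with an \code{id} column followed by either
#' \code{pheno1}, \code{pheno2} (bivariate panel) or \code{visit1} ..
#' \code{visit4}; the missing-value code is \code{NA}.
#'
#' @param path file path.
#' @return \code{readPhenotypes} returns a \linkS4class{PhenotypePanel} for
#'   bivariate files and a data.frame for four-visit files.
#' @export
readPhenotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
  if (all(c("pheno1", "pheno2") %in% names(tab)))
    return(PhenotypePanel(ids = tab$id, pheno1 = tab$pheno1,
                          pheno2 = tab$pheno2))
  if (all(paste0("visit", 1:4) %in% names(tab))) {
    tab$id <- as.character(tab$id)
    return(tab[c("id", paste0("visit", 1:4))])
  }
  stop("phenotype file must have columns pheno1/pheno2 or visit1..visit4")
}

#' @rdname readPhenotypes
#' @param x a \linkS4class{PhenotypePanel}, \linkS4class{ImputedPanel} or a
#'   four-visit data.frame. For an \linkS4class{ImputedPanel}, entry
#'   provenance is written to a sibling file \code{<path>.provenance}.
#' @export
writePhenotypes <- function(x, path) {
  if (is(x, "PhenotypePanel")) {
    v <- phenoValues(x)
    df <- data.frame(id = panelIds(x), pheno1 = v[, 1L], pheno2 = v[, 2L])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (is(x, "ImputedPanel")) {
      pr <- provenance(x)
      write.table(data.frame(id = panelIds(x), pheno1 = pr[, 1L],
                             pheno2 = pr[, 2L]),
                  paste0(path, ".provenance"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write additive-dosage matrices as TSV
#'
#' Rows are SNPs, columns are samples; the first column \code{snp} carries
#' variant ids. \code{readDosageTSV} returns the transposed sample x SNP
#' matrix expected by \code{\link{scanGenotypes}}.
#'
#' @param path file path.
#' @return numeric matrix, samples in rows, SNPs in columns.
#' @export
readDosageTSV <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  snp <- as.character(tab[[1L]])
  m <- t(as.matrix(tab[, -1L, drop = FALSE]))
  colnames(m) <- snp
  m
}

#' @rdname readDosageTSV
#' @param G sample x SNP dosage matrix (sample ids as row names).
#' @export
writeDosageTSV <- function(G, path) {
  df <- data.frame(snp = colnames(G), t(G), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read additive dosages from a VCF
#'
#' Extracts GT fields from a VCF and converts them to additive 0/1/2 dosage
#' counts of the alternate allele (missing genotypes become \code{NA}).
#'
#' @param path VCF file path (plain or bgzipped).
#' @return numeric matrix, samples in rows, variants in columns.
#' @export
readDosageVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  }
  m <- apply(gt, 2L, count)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  out <- t(m)
  colnames(out) <- rownames(gt)
  out
}
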