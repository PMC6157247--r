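## Mixed-model association: outcome construction, null model, score test.

#' Construct the analysis outcome from a four-visit table
#'
#' \code{average_difference} is the mean of the (log-scale) pre-treatment
#' visits 1 and 2 minus the mean of the post-treatment visits 3 and 4;
#' \code{single_difference} is visit 1 minus visit 3. Inputs are expected
#' already on the log scale.
#'
#' @param visits data.frame with columns \code{id}, \code{visit1} ..
#'   \code{visit4}.
#' @param definition \code{"average_difference"} or
#'   \code{"single_difference"}.
#' @return named numeric vector (names = ids) with attribute
#'   \code{"definition"}.
#' @export
computeOutcome <- function(visits,
                           definition = c("average_difference",
                                          "single_difference")) {
  definition <- match.arg(definition)
  need <- if (definition == "average_difference") paste0("visit", 1:4)
          else c("visit1", "visit3")
  vm <- as.matrix(visits[intersect(paste0("visit", 1:4), names(visits))])
  if (anyNA(vm[, need]))
    stop("missing values in ", paste(need, collapse = "/"),
         "; impute (imputePanel/carryoverFill) before computing outcomes")
  out <- if (definition == "average_difference")
    (visits$visit1 + visits$visit2) / 2 - (visits$visit3 + visits$visit4) / 2
  else visits$visit1 - visits$visit3
  out <- setNames(out, visits$id)
  attr(out, "definition") <- definition
  out
}

#' Fit the null linear mixed model with a pedigree random effect
#'
#' Maximum-likelihood fit of \code{y ~ N(1 b0, tau * phi + sigma2 * I)}: an
#' intercept-only model whose random effect captures familial correlation
#' through the relationship matrix. After one eigendecomposition
#' \code{phi = U D U'} the likelihood is profiled over the variance ratio
#' \code{lambda = tau / sigma2} in the rotated coordinates, so each
#' likelihood evaluation is O(n).
#'
#' @param outcome named numeric vector; names must match the phi dimnames
#'   (order is aligned internally when names are present).
#' @param phi relationship matrix.
#' @param lambdaRange search interval for log10(lambda).
#' @param eigenPhi optional precomputed \code{eigen(phi, symmetric = TRUE)},
#'   reusable across outcomes measured on the same samples.
#' @return object of class \code{"polygenicNull"}: a list with \code{beta0},
#'   \code{tau}, \code{sigma2}, \code{loglik}, \code{n} and rotated
#'   quantities reused by \code{\link{scoreTest}}.
#' @export
fitNullModel <- function(outcome, phi, lambdaRange = c(-6, 6),
                         eigenPhi = NULL) {
  y <- as.numeric(outcome)
  n <- length(y)
  if (nrow(phi) != n) stop("outcome and phi dimensions differ")
  if (!is.null(names(outcome)) && !is.null(rownames(phi))) {
    if (!setequal(names(outcome), rownames(phi)))
      stop("outcome names and phi ids differ")
    phi <- phi[names(outcome), names(outcome), drop = FALSE]
  }
  if (var(y) < 1e-12) stop("outcome is (numerically) constant; variance is degenerate")
  eg <- if (is.null(eigenPhi)) eigen((phi + t(phi)) / 2, symmetric = TRUE)
        else eigenPhi
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)[, 1L]
  xt <- crossprod(eg$vectors, rep(1, n))[, 1L]

  profile <- function(lambda) {
    w <- 1 / (lambda * d + 1)
    sxx <- sum(w * xt * xt)
    beta <- sum(w * xt * yt) / sxx
    r <- yt - xt * beta
    s2 <- sum(w * r * r) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(lambda * d + 1)) + n)
    list(ll = ll, beta = beta, s2 = s2)
  }
  obj <- function(loglam) profile(10^loglam)$ll
  opt <- optimize(obj, interval = lambdaRange, maximum = TRUE, tol = 1e-8)
  bestLam <- if (profile(0)$ll >= opt$objective) 0 else 10^opt$maximum
  pr <- profile(bestLam)
  sigma2 <- pr$s2
  tau <- bestLam * sigma2
  w <- 1 / (bestLam * d + 1) / sigma2      # diag of Sigma^-1 in rotated basis
  structure(list(beta0 = pr$beta, tau = tau, sigma2 = sigma2,
                 loglik = pr$ll, n = n,
                 U = eg$vectors, d = d, w = w,
                 yt = yt, xt = xt, rt = yt - xt * pr$beta,
                 ids = rownames(phi)),
            class = "polygenicNull")
}

#' @export
print.polygenicNull <- function(x, ...) {
  cat(sprintf("Polygenic null model (n = %d)\n", x$n))
  cat(sprintf("  beta0 = %.4g, tau (genetic) = %.4g, sigma2 (residual) = %.4g\n",
              x$beta0, x$tau, x$sigma2))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

.scanCore <- function(null, G) {
  ## G: samples x SNPs dosage matrix, already aligned with the null model.
  Gt <- crossprod(null$U, G)                     # rotated genotypes
  w <- null$w
  wr <- w * null$rt
  wx <- w * null$xt
  sxx <- sum(wx * null$xt)
  U1 <- as.numeric(crossprod(Gt, wr))            # score
  a <- colSums(w * Gt * Gt)
  b <- as.numeric(crossprod(Gt, wx))
  V <- a - b * b / sxx                           # null variance of the score
  stat <- U1 * U1 / V
  mono <- apply(G, 2L, function(g) var(g) < .Machine$double.eps)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  beta <- U1 / V
  se <- 1 / sqrt(V)
  stat[mono] <- NA_real_; p[mono] <- NA_real_
  beta[mono] <- NA_real_; se[mono] <- NA_real_
  data.frame(snp = if (is.null(colnames(G))) paste0("snp", seq_len(ncol(G)))
                   else colnames(G),
             beta = beta, se = se, stat = stat, p = p,
             n = null$n, monomorphic = mono,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score test of one SNP against a fitted null model
#'
#' One-degree-of-freedom score test of an additively coded SNP against the
#' polygenic null model: the statistic is \code{U^2 / V} with
#' \code{U = g' Sigma^{-1} (y - X b0)} and V its null variance after
#' projecting out the intercept; the p-value is the upper tail of the 1-df
#' chi-square. Only the null model fit is required, so one fit serves all
#' SNPs of a dataset. A monomorphic SNP yields \code{p = NA} with the
#' \code{monomorphic} flag set rather than an error.
#'
#' @param null a \code{"polygenicNull"} fit from \code{\link{fitNullModel}}.
#' @param g numeric dosage vector in [0, 2], aligned with the null model's
#'   samples.
#' @param snpID label for the output row.
#' @return one-row data.frame with columns \code{snp}, \code{beta} (effect
#'   per allele), \code{se}, \code{stat}, \code{p}, \code{n},
#'   \code{monomorphic}.
#' @export
scoreTest <- function(null, g, snpID = "snp") {
  if (any(g < -1e-9 | g > 2 + 1e-9, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  G <- matrix(as.numeric(g), ncol = 1L, dimnames = list(NULL, snpID))
  .scanCore(null, G)
}

#' Score tests across a genotype matrix
#'
#' Vectorized \code{\link{scoreTest}} over the columns of a dosage matrix.
#'
#' @param null a \code{"polygenicNull"} fit.
#' @param G numeric matrix, samples in rows and SNPs in columns; row names,
#'   when present, must match the null model's sample ids.
#' @return data.frame with one row per SNP (see \code{\link{scoreTest}}).
#' @export
scanGenotypes <- function(null, G) {
  G <- as.matrix(G)
  if (nrow(G) != null$n) stop("genotype rows must match the null model's n")
  if (!is.null(rownames(G)) && !is.null(null$ids))
    G <- G[null$ids, , drop = FALSE]
  .scanCore(null, G)
}

#' Write association results as TSV
#'
#' @param results data.frame from \code{\link{scanGenotypes}}.
#' @param path file path.
#' @export
writeAssociation <- function(results, path) {
  write.table(results[c("snp", "beta", "se", "stat", "p", "n")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
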