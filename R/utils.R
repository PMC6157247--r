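## Internal helpers shared across modules.

## Run code under a temporary RNG seed, restoring the caller's RNG state.
## seed = NULL means "use the current RNG stream untouched".
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

## Derive a stream of child seeds from one seed (kept below 2^31).
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Round half away from zero (documented choice for missingness counts).
.roundHalfUp <- function(x) floor(x + 0.5)

## Connected components of the relatedness graph |phi| > tol.
## Returns an integer vector of component labels along the ids of phi.
.phiComponents <- function(phi, tol = 1e-12) {
  n <- nrow(phi)
  comp <- integer(n)
  cur <- 0L
  adj <- abs(phi) > tol
  diag(adj) <- FALSE
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

## Cholesky with escalating diagonal jitter (<= 3 steps), as used for
## conditional-mean solves on nearly singular observed blocks.
.cholJitter <- function(S, steps = 3L, rel = 1e-8) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  k <- 0L
  base <- rel * mean(diag(S))
  if (!is.finite(base) || base <= 0) base <- rel
  while (is.null(out) && k < steps) {
    k <- k + 1L
    out <- tryCatch(chol(S + diag(base * 10^(k - 1L), nrow(S))),
                    error = function(e) NULL)
  }
  out
}

## Quadratic form solve via a Cholesky factor: returns solve(S, b) pieces.
## U is chol(S) (upper). Works for b a vector or matrix.
.cholSolve <- function(U, b) backsolve(U, backsolve(U, b, transpose = TRUE))

.logdetFromChol <- function(U) 2 * sum(log(diag(U)))

## Draw k of n indices uniformly without replacement, deterministically
## under seed; count is round-half-up of fraction * n.
.maskIndices <- function(n, fraction, seed = NULL) {
  k <- .roundHalfUp(fraction * n)
  .withSeed(seed, sample.int(n, k))
}
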