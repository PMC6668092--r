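#' Draw normalized Rademacher probe vectors
#'
#' Probes for Hutchinson-type stochastic trace estimation: i.i.d. vectors
#' whose entries are +1/sqrt(n) or -1/sqrt(n) with equal probability, so
#' each probe has unit 2-norm and \code{E[v v^T] = I/n}.
#'
#' @param n dimension.
#' @param nRand number of probes (>= 1); default 15.
#' @param seed integer seed; identical seeds give identical probes.
#' @return a \code{ProbeSet}.
#' @export
drawProbes <- function(n, nRand = 15L, seed = 1L) {
  if (nRand < 1L) stop("nRand must be at least 1")
  V <- withSeed(seed, {
    matrix(sample(c(-1, 1), n * nRand, replace = TRUE), n, nRand) / sqrt(n)
  })
  new("ProbeSet", V = V, seed = as.numeric(seed))
}

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Gaussian quadrature from a Lanczos Jacobi matrix
#'
#' Spectral decomposition of the tridiagonal Jacobi matrix T of one
#' factorization yields an m-point Gaussian quadrature for the spectral
#' measure of (A, v): nodes are the eigenvalues of T and weights the
#' squared first components of its (orthonormal) eigenvectors, which sum
#' to one. The matrices are tiny (m = number of Lanczos steps), so the
#' eigendecomposition is computationally trivial.
#'
#' @param fact a \code{LanczosFactorization} (>= 1 step).
#' @return list with numeric \code{nodes} and \code{weights}.
#' @export
jacobiQuadrature <- function(fact) {
  stopifnot(is(fact, "LanczosFactorization"))
  T <- jacobiMatrix(fact@alpha, fact@beta)
  ed <- eigen(T, symmetric = TRUE)
  list(nodes = ed$values, weights = as.numeric(ed$vectors[1L, ])^2)
}

#' Assemble quadrature rules for a probe block
#'
#' @param blockFact a \code{BlockFactorization} whose seeds are the probe
#'   vectors.
#' @param n operator dimension.
#' @return a \code{QuadratureRule}.
#' @export
quadratureRules <- function(blockFact, n) {
  qs <- lapply(factorizations(blockFact), jacobiQuadrature)
  new("QuadratureRule",
      nodes = lapply(qs, `[[`, "nodes"),
      weights = lapply(qs, `[[`, "weights"),
      n = as.integer(n))
}

#' Stochastic Lanczos quadrature log-determinant
#'
#' Estimates \code{ln det(H_0 + sigma I)} as
#' \code{(n / n_rand) * sum_k sum_l w_kl * ln(theta_kl + sigma)} from
#' quadrature rules built once at the base operator. Because a spectral
#' shift moves every node by sigma and leaves the weights untouched, the
#' whole shift family is covered by pure vector arithmetic with no
#' further operator applications.
#'
#' @param rules a \code{QuadratureRule}.
#' @param sigma nonnegative shift.
#' @return log-determinant estimate (nats).
#' @export
slqLogDet <- function(rules, sigma) {
  stopifnot(is(rules, "QuadratureRule"))
  nRand <- length(rules@nodes)
  total <- 0
  for (k in seq_len(nRand)) {
    th <- rules@nodes[[k]] + sigma
    if (any(th <= 0))
      stop("operator is not positive definite at this shift")
    total <- total + sum(rules@weights[[k]] * log(th))
  }
  rules@n / nRand * total
}

setMethod("show", "ProbeSet", function(object) {
  cat(sprintf("ProbeSet: %d normalized Rademacher probes of dimension %d (seed %g)\n",
              ncol(object@V), nrow(object@V), object@seed))
})

setMethod("show", "QuadratureRule", function(object) {
  ks <- lengths(object@nodes)
  cat(sprintf("QuadratureRule: %d probes, %d-%d nodes each (n = %d)\n",
              length(ks), min(ks), max(ks), object@n))
})
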