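#' Draw Monte Carlo latent samples for first-order REML
#'
#' Samples the latent variables used to approximate the expected BLUP
#' norms: per sample k, a genetic part \code{g_k = m^{-1/2} S Z u_k} with
#' \code{u_k ~ N(0, I_m)}, and a residual part \code{e_k = S w_k} with
#' \code{w_k ~ N(0, I_n)} (idempotence of S makes \code{Cov(e_k) = S}).
#' The Monte Carlo phenotype at variance ratio tau is assembled by
#' linearity as \code{y_k(tau) = g_k + sqrt(tau) e_k}, whose covariance
#' restricted to the range of S is exactly the model covariance at
#' \code{(sigma_g^2 = 1, tau)}. Both parts are kept as separate seed
#' vectors so one Lanczos round covers every tau. Every sample lies in
#' the range of S.
#'
#' @param Z standardized genotype matrix (n x m) or
#'   \code{StandardizedGenotypes}.
#' @param projector covariate \code{Projector} S.
#' @param nRand number of samples.
#' @param seed integer seed (independent of the SLQ probe stream).
#' @return list with \code{G} (n x nRand genetic parts), \code{E}
#'   (n x nRand residual parts), \code{U} (m x nRand latent SNP effects)
#'   and \code{seed}.
#' @export
drawMCPhenotypes <- function(Z, projector, nRand = 15L, seed = 1L) {
  if (is(Z, "StandardizedGenotypes")) Z <- Z@Z
  if (nRand < 1L) stop("nRand must be at least 1")
  n <- nrow(Z)
  m <- ncol(Z)
  withSeed(seed, {
    U <- matrix(rnorm(m * nRand), m, nRand)
    W <- matrix(rnorm(n * nRand), n, nRand)
    E <- projectOut(projector, W)
    G <- projectOut(projector, Z %*% U) / sqrt(m)
    list(G = G, E = E, U = U, seed = as.numeric(seed))
  })
}

#' Assemble Monte Carlo phenotypes at a variance ratio
#'
#' @param samples output of \code{\link{drawMCPhenotypes}}.
#' @param tau variance ratio.
#' @return n x nRand matrix \code{G + sqrt(tau) E}.
#' @export
mcPhenotypes <- function(samples, tau) {
  samples$G + sqrt(tau) * samples$E
}

#' BLUPs of SNP effects and residuals at a variance ratio
#'
#' Best linear unbiased predictions under the projected model:
#' \code{u(tau) = m^{-1/2} Zt S H_tau^{-1} S y} and
#' \code{e(tau) = tau H_tau^{-1} S y}, with
#' \code{H_tau = (1/m) S Z Zt S + tau I}. The inverse is taken through
#' the stored Lanczos factorization of the projected seed system
#' (\code{lSolve}; zero operator applications) followed by the single
#' unavoidable Zt-product for the SNP effects.
#'
#' @param fact \code{LanczosFactorization} of the projected operator with
#'   the (projected) phenotype as seed.
#' @param sigma nonnegative shift \code{tau - tau0}.
#' @param tau variance ratio at which the BLUPs are evaluated.
#' @param Z standardized genotype matrix or \code{StandardizedGenotypes}.
#' @param projector covariate \code{Projector}.
#' @param ztCounter optional environment with field \code{n}; incremented
#'   by one per Zt-product for cost audits.
#' @return list with \code{u} (length m) and \code{e} (length n).
#' @export
blup <- function(fact, sigma, tau, Z, projector, ztCounter = NULL) {
  if (is(Z, "StandardizedGenotypes")) Z <- Z@Z
  x <- lSolve(fact, sigma)
  if (!is.null(ztCounter)) ztCounter$n <- ztCounter$n + 1L
  u <- drop(crossprod(Z, projectOut(projector, x))) / sqrt(ncol(Z))
  list(u = u, e = tau * x)
}

#' Precompute the first-order Monte Carlo REML state
#'
#' One overhead round: a block Lanczos factorization of the projected
#' operator \code{H = (1/m) S Z Zt S + tau0 I} over 2 nRand + 1 seed
#' systems — the observed projected phenotype plus the genetic and
#' residual parts of each Monte Carlo sample (kept separate so that the
#' tau-dependent Monte Carlo phenotype solves follow by linearity). All
#' subsequent root-statistic evaluations reuse these factorizations.
#'
#' @inheritParams fitFOMC
#' @return an opaque state list for \code{\link{fRootStatistic}}.
#' @export
fomcState <- function(y, X, Z, space = parameterSpace(), nRand = 15L,
                      lanczosTol = 5e-5, seed = 1L, maxIter = NULL) {
  if (!is(Z, "StandardizedGenotypes"))
    stop("the first-order Monte Carlo algorithm requires the genotype matrix (a StandardizedGenotypes object); a precomputed GRM is not sufficient")
  geno <- Z
  X <- as.matrix(X)
  n <- length(y)
  proj <- makeProjector(X)
  c <- proj@rank
  Sy <- projectOut(proj, y)
  if (sqrt(sum(Sy^2)) <= 1e-12 * sqrt(sum(y^2)))
    stop("phenotype lies in the covariate column space")
  opProj <- makeOperator(geno, space$tau0, projector = proj)
  samples <- drawMCPhenotypes(geno, proj, nRand, seed)
  seeds <- cbind(Sy, samples$G, samples$E)
  block <- blockLanczosSeed(opProj, seeds, lanczosTol, maxIter)
  facts <- factorizations(block)
  warn <- character(0)
  notConv <- which(!vapply(facts, function(f) f@converged, logical(1)))
  if (length(notConv)) {
    warn <- sprintf("%d Lanczos factorization(s) hit the iteration cap",
                    length(notConv))
    warning(warn)
  }
  ztCounter <- new.env(parent = emptyenv())
  ztCounter$n <- 0L
  list(space = space, n = n, c = c, nRand = nRand, proj = proj, Sy = Sy,
       Z = geno@Z, opProj = opProj, samples = samples,
       yFact = facts[[1L]],
       gFacts = facts[1L + seq_len(nRand)],
       eFacts = facts[1L + nRand + seq_len(nRand)],
       ztCounter = ztCounter,
       lanczosIters = vapply(facts, function(f) f@steps, integer(1)),
       warnings = warn)
}

#' First-order REML root statistic f_r
#'
#' At stationary points of the REML criterion the expected squared norms
#' of the BLUPs match their observed values; the statistic
#' \code{f_r(tau) = ln[(ut u)/(et e)] - ln[E_MC(ut u)/E_MC(et e)]}
#' compares the observed BLUP norm ratio against its Monte Carlo
#' expectation under the model at the same tau (the overall variance
#' scale cancels in the ratio), and its root is the REML estimate.
#' Evaluation reuses the stored factorizations: shifted tridiagonal
#' solves plus one Zt-product per BLUP, no operator applications.
#'
#' @param state state list from \code{\link{fomcState}}.
#' @param h2 heritability at which to evaluate.
#' @return scalar value of the root statistic.
#' @export
fRootStatistic <- function(state, h2) {
  sp <- state$space
  tau <- h2ToTau(h2)
  sigma <- max(tau - sp$tau0, 0)
  m <- ncol(state$Z)
  n <- state$n
  xObs <- lSolve(state$yFact, sigma)
  Xg <- vapply(state$gFacts, function(f) lSolve(f, sigma), numeric(n))
  Xe <- vapply(state$eFacts, function(f) lSolve(f, sigma), numeric(n))
  Xmc <- Xg + sqrt(tau) * Xe          # solves for y_k(tau) by linearity
  Xall <- cbind(xObs, Xmc)
  state$ztCounter$n <- state$ztCounter$n + ncol(Xall)
  Uall <- crossprod(state$Z, projectOut(state$proj, Xall)) / sqrt(m)
  uu <- colSums(Uall^2)
  ee <- tau^2 * colSums(Xall^2)
  uuObs <- uu[1L]
  eeObs <- ee[1L]
  uuMC <- mean(uu[-1L])
  eeMC <- mean(ee[-1L])
  if (min(uuObs, eeObs, uuMC, eeMC) <= 0)
    stop("degenerate BLUP quadratic term in the root statistic")
  log(uuObs / eeObs) - log(uuMC / eeMC)
}

#' Fit the two-component model by Lanczos first-order Monte Carlo REML
#'
#' One overhead round of block Lanczos work over the observed phenotype
#' and the Monte Carlo latent samples at the base shift, then bracketed
#' root-finding (Brent) of the first-order statistic \code{f_r} on the
#' heritability scale. Each iteration after setup costs one Zt-product
#' per BLUP and no operator applications. Requires the genotype matrix
#' (the BLUPs of SNP effects cannot be formed from a GRM alone).
#'
#' @param y phenotype vector.
#' @param X covariate matrix including intercept.
#' @param Z \code{StandardizedGenotypes}.
#' @param space heritability interval from \code{\link{parameterSpace}}.
#' @param nRand number of Monte Carlo samples (default 15).
#' @param lanczosTol absolute Lanczos residual tolerance (default 5e-5).
#' @param optTol absolute tolerance on h2 for the root finder (default 1e-5).
#' @param seed integer seed for the Monte Carlo latent stream.
#' @param maxIter Lanczos iteration cap.
#' @param returnState also return the state list.
#' @return a \code{REMLResult}, or a list \code{(result, state)} when
#'   \code{returnState = TRUE}.
#' @export
fitFOMC <- function(y, X, Z, space = parameterSpace(), nRand = 15L,
                    lanczosTol = 5e-5, optTol = 1e-5, seed = 1L,
                    maxIter = NULL, returnState = FALSE) {
  state <- fomcState(y, X, Z, space, nRand, lanczosTol, seed, maxIter)
  nEval <- 0L
  f <- function(h2) {
    nEval <<- nEval + 1L
    fRootStatistic(state, h2)
  }
  eps <- min(1e-8, (space$h2Max - space$h2Min) / 100)
  lo <- space$h2Min + eps
  hi <- space$h2Max - eps
  fLo <- f(lo)
  fHi <- f(hi)
  warn <- state$warnings
  boundary <- FALSE
  if (is.finite(fLo) && is.finite(fHi) && sign(fLo) != sign(fHi)) {
    root <- uniroot(f, c(lo, hi), f.lower = fLo, f.upper = fHi,
                    tol = optTol)
    h2hat <- root$root
  } else {
    h2hat <- if (abs(fLo) < abs(fHi)) lo else hi
    boundary <- TRUE
    warn <- c(warn, "no root of f_r in the heritability range; boundary value returned")
    warning("no sign change of f_r in [h2Min, h2Max]; returning boundary value")
  }
  tau <- h2ToTau(h2hat)
  sigma <- max(tau - space$tau0, 0)
  ypy <- sum(state$Sy * lSolve(state$yFact, sigma))
  vc <- profileVarianceComponents(ypy, tau, state$n, state$c)
  res <- new("REMLResult",
             h2 = tauToH2(tau), sigmaG2 = vc$sigmaG2, sigmaE2 = vc$sigmaE2,
             logLik = NA_real_, nEval = nEval,
             lanczosIters = state$lanczosIters, algorithm = "fomc",
             boundary = boundary, warnings = warn)
  if (returnState) list(result = res, state = state) else res
}
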