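#' Heritability / variance-ratio reparametrization
#'
#' The single free parameter after profiling out the genetic variance is
#' the ratio \code{tau = sigma_e^2 / sigma_g^2}; optimization is carried
#' out on the heritability scale \code{h2 = 1/(1 + tau)}, which is
#' bounded and has a natural tolerance.
#'
#' @param h2 heritability in (0, 1).
#' @return \code{tau = (1 - h2)/h2}.
#' @export
h2ToTau <- function(h2) {
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)")
  (1 - h2) / h2
}

#' @rdname h2ToTau
#' @param tau variance ratio > 0.
#' @export
tauToH2 <- function(tau) {
  if (any(tau < 0)) stop("tau must be nonnegative")
  1 / (1 + tau)
}

#' Heritability search interval as a shifted family
#'
#' Anchors the base operator at \code{tau0 = (1 - h2Max)/h2Max}, the
#' smallest variance ratio in the search range, so that every parameter
#' value visited maps to a nonnegative spectral shift
#' \code{sigma = tau - tau0} and the condition number of the shifted
#' operator never exceeds that of the base operator.
#'
#' @param h2Min,h2Max heritability bounds, 0 < h2Min < h2Max < 1.
#'   Defaults 0.01 and 0.99.
#' @return list with \code{h2Min}, \code{h2Max}, \code{tau0}.
#' @export
parameterSpace <- function(h2Min = 0.01, h2Max = 0.99) {
  if (!(h2Min > 0 && h2Max < 1 && h2Min < h2Max))
    stop("need 0 < h2Min < h2Max < 1")
  list(h2Min = h2Min, h2Max = h2Max, tau0 = (1 - h2Max) / h2Max)
}

#' Profiled variance components at a given variance ratio
#'
#' The REML stationarity conditions give the genetic variance analytically
#' once tau is fixed: \code{sigma_g^2 = yt P y / (n - c)} and
#' \code{sigma_e^2 = tau * sigma_g^2}.
#'
#' @param ypy quadratic form yt P_tau y, > 0.
#' @param tau variance ratio.
#' @param n sample size; \code{c} covariate count (n > c).
#' @param c covariate count.
#' @return named list \code{sigmaG2}, \code{sigmaE2}.
#' @export
profileVarianceComponents <- function(ypy, tau, n, c) {
  if (ypy <= 0) stop("quadratic form must be positive (degenerate phenotype)")
  if (n <= c) stop("need n > c")
  sigmaG2 <- ypy / (n - c)
  list(sigmaG2 = sigmaG2, sigmaE2 = tau * sigmaG2)
}

#' Precompute the SLDF-REML criterion state
#'
#' One overhead round of (block) Lanczos work at the base shift, after
#' which the profiled REML criterion is evaluable for any heritability in
#' the search range using vector operations only:
#' \itemize{
#'   \item SLQ probe factorizations and quadrature rules over the
#'     unprojected base operator H_0 (for \code{ln det(H_tau)});
#'   \item a block factorization with the covariate columns as seeds over
#'     H_0 (for \code{ln det(Xt H_tau^(-1) X)});
#'   \item a single factorization of the projected system
#'     \code{(S H_0 S) x = S y} (for the quadratic form, via the
#'     pseudo-inverse identity that reduces it to a shifted solve).
#' }
#' The constant \code{ln det(XtX)} term is dropped throughout.
#'
#' @param y phenotype vector.
#' @param X covariate matrix including an intercept column.
#' @param source \code{StandardizedGenotypes} or explicit GRM matrix.
#' @param space output of \code{\link{parameterSpace}}.
#' @param nRand number of SLQ probes (default 15).
#' @param lanczosTol absolute Lanczos residual tolerance (default 5e-5).
#' @param seed integer seed for the probe stream.
#' @param maxIter Lanczos iteration cap.
#' @return an opaque criterion state list for \code{\link{remlCriterion}}.
#' @export
remlCriterionState <- function(y, X, source, space = parameterSpace(),
                               nRand = 15L, lanczosTol = 5e-5,
                               seed = 1L, maxIter = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  proj <- makeProjector(X)
  c <- proj@rank
  Sy <- projectOut(proj, y)
  if (sqrt(sum(Sy^2)) <= 1e-12 * sqrt(sum(y^2)))
    stop("phenotype lies in the covariate column space")
  opH0 <- makeOperator(source, space$tau0)
  opProj <- makeOperator(source, space$tau0, projector = proj)
  probes <- drawProbes(n, nRand, seed)
  probeFacts <- blockLanczosSeed(opH0, probes@V, lanczosTol, maxIter)
  rules <- quadratureRules(probeFacts, n)
  covFacts <- blockLanczosSeed(opH0, X, lanczosTol, maxIter)
  yFact <- lanczosSeed(opProj, Sy, lanczosTol, maxIter)
  allFacts <- c(factorizations(probeFacts), factorizations(covFacts),
                list(yFact))
  warn <- character(0)
  notConv <- which(!vapply(allFacts, function(f) f@converged, logical(1)))
  if (length(notConv)) {
    finals <- vapply(allFacts[notConv],
                     function(f) f@resHistory[f@steps], numeric(1))
    warn <- sprintf(
      "%d Lanczos factorization(s) hit the iteration cap (final residuals up to %.3e)",
      length(notConv), max(finals))
    warning(warn)
  }
  list(space = space, n = n, c = c, X = X, Sy = Sy,
       proj = proj, opH0 = opH0, opProj = opProj,
       probes = probes, rules = rules,
       covFacts = covFacts, yFact = yFact,
       lanczosIters = vapply(allFacts, function(f) f@steps, integer(1)),
       warnings = warn)
}

#' Quadratic form yt P_tau y via the projected seed system
#'
#' Uses the identity
#' \code{yt S pinv(S H_tau S) S y = yt S inv(S H_0 S + sigma I) S y}
#' so that one stored factorization of the projected system covers every
#' shift with an O(n k) tridiagonal solve.
#'
#' @param state criterion state from \code{\link{remlCriterionState}}.
#' @param sigma nonnegative shift \code{tau - tau0}.
#' @return scalar quadratic form (phenotype-variance units).
#' @export
quadraticForm <- function(state, sigma) {
  x <- lSolve(state$yFact, sigma)
  sum(state$Sy * x)
}

#' Covariate log-determinant term ln det(Xt H_tau^(-1) X)
#'
#' Solves the c shifted covariate systems from the stored block
#' factorization, forms the small c x c matrix Xt H_tau^(-1) X and takes
#' its log-determinant through a Cholesky factorization.
#'
#' @param state criterion state.
#' @param sigma nonnegative shift.
#' @return scalar log-determinant (nats).
#' @export
covariateLogDetTerm <- function(state, sigma) {
  facts <- factorizations(state$covFacts)
  Xsol <- vapply(facts, function(f) lSolve(f, sigma), numeric(state$n))
  M <- crossprod(state$X, Xsol)
  M <- (M + t(M)) / 2
  R <- tryCatch(chol(M), error = function(e)
    stop("X' H^{-1} X is not positive definite (non-converged solves?)"))
  2 * sum(log(diag(R)))
}

#' Profiled REML criterion at a heritability value
#'
#' Evaluates (up to an additive constant)
#' \code{l(h2) = -(n - c) ln(yt P_tau y) - [lndet(H_tau) + lndet(Xt H_tau^(-1) X)]}
#' with \code{tau = (1-h2)/h2}, the profiled form of the restricted log
#' likelihood in which the genetic variance has been replaced by its
#' stationary value. All three terms come from stored factorizations:
#' no operator applications are performed.
#'
#' @param state criterion state.
#' @param h2 heritability in the search range.
#' @return profiled log likelihood (nats, up to a constant).
#' @export
remlCriterion <- function(state, h2) {
  sp <- state$space
  if (h2 < sp$h2Min - 1e-12 || h2 > sp$h2Max + 1e-12)
    stop("h2 outside the parameter space")
  tau <- h2ToTau(h2)
  sigma <- max(tau - sp$tau0, 0)
  ypy <- quadraticForm(state, sigma)
  ld <- slqLogDet(state$rules, sigma) + covariateLogDetTerm(state, sigma)
  -(state$n - state$c) * log(ypy) - ld
}

#' Fit the two-component model by stochastic Lanczos derivative-free REML
#'
#' One overhead round of block Lanczos factorizations at the base shift
#' (SLQ probes, covariate columns, and the projected phenotype seed),
#' then Brent maximization of the profiled REML criterion over the
#' heritability interval; every criterion evaluation after setup costs
#' only vector operations.
#'
#' @param y phenotype vector.
#' @param X covariate matrix including intercept.
#' @param source \code{StandardizedGenotypes} (implicit mode) or
#'   precomputed GRM matrix (explicit mode).
#' @param space heritability interval from \code{\link{parameterSpace}}.
#' @param nRand number of SLQ probes (default 15).
#' @param lanczosTol absolute Lanczos residual tolerance (default 5e-5).
#' @param optTol absolute tolerance on h2 for the optimizer (default 1e-5).
#' @param seed integer seed for the probe stream.
#' @param maxIter Lanczos iteration cap (default \code{min(n, 1000)}).
#' @param returnState also return the criterion state (for diagnostics).
#' @return a \code{REMLResult}, or when \code{returnState = TRUE} a list
#'   with elements \code{result} and \code{state}.
#' @export
fitSLDF <- function(y, X, source, space = parameterSpace(),
                    nRand = 15L, lanczosTol = 5e-5, optTol = 1e-5,
                    seed = 1L, maxIter = NULL, returnState = FALSE) {
  state <- remlCriterionState(y, X, source, space, nRand, lanczosTol,
                              seed, maxIter)
  nEval <- 0L
  obj <- function(h2) {
    nEval <<- nEval + 1L
    remlCriterion(state, h2)
  }
  opt <- optimize(obj, c(space$h2Min, space$h2Max), maximum = TRUE,
                  tol = optTol)
  h2hat <- opt$maximum
  warn <- state$warnings
  boundary <- (h2hat - space$h2Min) < 2 * optTol ||
              (space$h2Max - h2hat) < 2 * optTol
  if (boundary)
    warn <- c(warn, "optimum on the heritability boundary")
  grid <- seq(space$h2Min, space$h2Max, length.out = 5L)
  lv <- vapply(grid, function(h) remlCriterion(state, h), numeric(1))
  if (max(lv) - min(lv) < 1e-7 * max(1, abs(mean(lv)))) {
    warn <- c(warn, "flat likelihood surface; heritability unidentifiable")
    warning("likelihood surface is flat in h2; heritability unidentifiable")
  }
  tau <- h2ToTau(h2hat)
  ypy <- quadraticForm(state, max(tau - space$tau0, 0))
  vc <- profileVarianceComponents(ypy, tau, state$n, state$c)
  res <- new("REMLResult",
             h2 = tauToH2(tau), sigmaG2 = vc$sigmaG2, sigmaE2 = vc$sigmaE2,
             logLik = opt$objective, nEval = nEval,
             lanczosIters = state$lanczosIters, algorithm = "sldf",
             boundary = boundary, warnings = warn)
  if (returnState) list(result = res, state = state) else res
}

setMethod("heritability", "REMLResult", function(x) x@h2)
setMethod("varianceComponents", "REMLResult", function(x)
  c(sigmaG2 = x@sigmaG2, sigmaE2 = x@sigmaE2))

setMethod("show", "REMLResult", function(object) {
  cat(sprintf("REMLResult (%s):\n", object@algorithm))
  cat(sprintf("  h2       = %.6f%s\n", object@h2,
              if (object@boundary) " [boundary]" else ""))
  cat(sprintf("  sigma_g2 = %.6f\n  sigma_e2 = %.6f\n",
              object@sigmaG2, object@sigmaE2))
  cat(sprintf("  logLik   = %.4f (up to constant), %d evaluations\n",
              object@logLik, object@nEval))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})
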