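#' Dense spectral-decomposition REML oracle
#'
#' Deterministic reference implementation for small problems: forms an
#' explicit orthonormal basis K of the complement of the covariate space,
#' eigendecomposes the projected covariance \code{K' GRM K} once, then
#' evaluates the exact profiled REML log likelihood
#' \code{l(h2) = -(n-c) ln(yt P_tau y) - ln det(Kt H_tau K)} on an h2
#' grid and refines the argmax by Brent search to an h2 tolerance of
#' 1e-8. Used as the trust anchor for every stochastic component.
#'
#' @param y phenotype vector.
#' @param X covariate matrix including intercept.
#' @param GRM dense symmetric positive semidefinite matrix (1/m) Z Zt.
#' @param space heritability interval from \code{\link{parameterSpace}}.
#' @param gridSize number of grid points (default 101).
#' @return list with \code{h2} (argmax), \code{result} (a
#'   \code{REMLResult}), \code{grid}, \code{logLik} (exact profiled
#'   values on the grid), \code{eigenvalues} of the projected covariance,
#'   \code{unidentifiable} and \code{boundary} flags.
#' @export
denseREML <- function(y, X, GRM, space = parameterSpace(),
                      gridSize = 101L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n > 3000L) stop("dense oracle is limited to n <= 3000")
  if (max(abs(GRM - t(GRM))) > 1e-8 * max(1, max(abs(GRM))))
    stop("GRM must be symmetric")
  K <- covariateComplementBasis(X)
  c <- n - ncol(K)
  M <- crossprod(K, GRM %*% K)
  M <- (M + t(M)) / 2
  ed <- eigen(M, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  yt <- drop(crossprod(ed$vectors, crossprod(K, y)))
  ll <- function(h2) {
    tau <- (1 - h2) / h2
    ypy <- sum(yt^2 / (d + tau))
    -(n - c) * log(ypy) - sum(log(d + tau))
  }
  grid <- seq(space$h2Min, space$h2Max, length.out = gridSize)
  lv <- vapply(grid, ll, numeric(1))
  unidentifiable <- (max(lv) - min(lv)) < 1e-9 * max(1, abs(mean(lv)))
  iBest <- which.max(lv)
  lo <- grid[max(iBest - 1L, 1L)]
  hi <- grid[min(iBest + 1L, gridSize)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  h2hat <- opt$maximum
  boundary <- (h2hat - space$h2Min) < 1e-4 * (space$h2Max - space$h2Min) ||
              (space$h2Max - h2hat) < 1e-4 * (space$h2Max - space$h2Min)
  tau <- (1 - h2hat) / h2hat
  ypy <- sum(yt^2 / (d + tau))
  sigmaG2 <- ypy / (n - c)
  warn <- character(0)
  if (unidentifiable) warn <- c(warn, "flat likelihood surface; heritability unidentifiable")
  if (boundary) warn <- c(warn, "optimum on the heritability boundary")
  res <- new("REMLResult", h2 = 1 / (1 + tau), sigmaG2 = sigmaG2,
             sigmaE2 = tau * sigmaG2, logLik = opt$objective,
             nEval = length(grid), lanczosIters = integer(0),
             algorithm = "dense", boundary = boundary, warnings = warn)
  list(h2 = h2hat, result = res, grid = grid, logLik = lv,
       eigenvalues = d, unidentifiable = unidentifiable,
       boundary = boundary)
}

# Explicit orthonormal basis K of the orthogonal complement of col(X),
# from the complete orthogonal decomposition of X.
covariateComplementBasis <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  qrx <- qr(X)
  r <- qrx$rank
  if (r >= n) stop("covariates span the whole space")
  Qfull <- qr.Q(qrx, complete = TRUE)
  Qfull[, (r + 1L):n, drop = FALSE]
}

#' Exact log-determinant of a shifted dense matrix
#'
#' \code{ln det(H + sigma I)} through a symmetric eigendecomposition;
#' errors if any shifted eigenvalue is nonpositive.
#'
#' @param H dense symmetric matrix.
#' @param sigma shift.
#' @return log-determinant (nats).
#' @export
exactLogDet <- function(H, sigma = 0) {
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev + sigma <= 0)) stop("matrix is not positive definite at this shift")
  sum(log(ev + sigma))
}

#' Exact projected quadratic form yt K (Kt H K)^(-1) Kt y
#'
#' Dense reference evaluation with an explicit complement basis K.
#'
#' @param y phenotype vector.
#' @param X covariate matrix.
#' @param H dense symmetric positive definite matrix.
#' @return scalar quadratic form.
#' @export
exactProjectedQuadForm <- function(y, X, H) {
  K <- covariateComplementBasis(X)
  M <- crossprod(K, H %*% K)
  M <- (M + t(M)) / 2
  Ky <- crossprod(K, y)
  drop(crossprod(Ky, solve(M, Ky)))
}
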