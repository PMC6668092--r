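# Tridiagonal solve (T + sigma I) y = e1 by the Thomas algorithm.
# T is SPD (Jacobi matrix of an SPD operator), so no pivoting is needed;
# a vanishing pivot signals a semidefinite or negatively shifted system.
solveTridiagE1 <- function(alpha, beta, sigma = 0) {
  k <- length(alpha)
  d <- alpha + sigma
  rhs <- c(1, rep(0, k - 1L))
  if (k == 1L) {
    if (abs(d) < .Machine$double.eps * max(1, abs(alpha)))
      stop("shifted Jacobi matrix is numerically singular")
    return(rhs / d)
  }
  cp <- numeric(k - 1L)
  dp <- numeric(k)
  dv <- d[1]
  if (abs(dv) < 1e-300) stop("shifted Jacobi matrix is numerically singular")
  cp[1] <- beta[1] / dv
  dp[1] <- rhs[1] / dv
  for (i in 2:k) {
    denom <- d[i] - beta[i - 1L] * cp[i - 1L]
    if (abs(denom) < 1e-300)
      stop("shifted Jacobi matrix is numerically singular")
    if (i < k) cp[i] <- beta[i] / denom
    dp[i] <- (rhs[i] - beta[i - 1L] * dp[i - 1L]) / denom
  }
  y <- numeric(k)
  y[k] <- dp[k]
  for (i in (k - 1L):1L) y[i] <- dp[i] - cp[i] * y[i + 1L]
  y
}

# Dense Jacobi matrix from recurrence coefficients (small, k x k).
jacobiMatrix <- function(alpha, beta) {
  k <- length(alpha)
  T <- diag(alpha, nrow = k)
  if (k > 1L) {
    idx <- seq_len(k - 1L)
    T[cbind(idx, idx + 1L)] <- beta
    T[cbind(idx + 1L, idx)] <- beta
  }
  T
}

#' @describeIn applyOperator plain dense symmetric matrix as operator
#'   (used by oracles and tests); applications are not counted.
setMethod("applyOperator", "matrix", function(op, v, count = TRUE) op %*% v)

#' Lanczos factorization of a seed system
#'
#' Runs the Lanczos process on \code{A x = b} with full
#' reorthogonalization, storing the orthonormal Krylov basis and the
#' tridiagonal Jacobi coefficients. Iteration stops when the conjugate
#' gradient residual norm of \code{A x = b} (recovered from the
#' tridiagonal recurrence, no extra operator work) drops below
#' \code{tol}, when the recurrence breaks down (an invariant subspace has
#' been captured, treated as happy termination), or at \code{maxIter}
#' steps, in which case the result is flagged unconverged but returned.
#'
#' Because Krylov subspaces are shift invariant, the stored factorization
#' solves every nonnegatively shifted system \code{(A + sigma I) x = b}
#' via \code{\link{lSolve}} in O(n k) vector operations.
#'
#' @param A a \code{GenomicOperator}, or a dense symmetric matrix.
#' @param b nonzero seed vector.
#' @param tol absolute residual 2-norm tolerance (default 5e-5).
#' @param maxIter maximum Lanczos steps (default \code{min(n, 1000)}).
#' @return a \code{LanczosFactorization}.
#' @export
lanczosSeed <- function(A, b, tol = 5e-5, maxIter = NULL) {
  n <- length(b)
  if (is.null(maxIter)) maxIter <- min(n, 1000L)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) stop("seed vector b must be nonzero")
  chunk <- 64L
  U <- matrix(0, n, min(chunk, maxIter))
  U[, 1L] <- b / bnorm
  alpha <- numeric(0)
  beta <- numeric(0)
  res <- numeric(0)
  converged <- FALSE
  k <- 0L
  breakdownTol <- 1e-13
  repeat {
    k <- k + 1L
    w <- applyOperator(A, U[, k])
    a <- sum(U[, k] * w)
    w <- w - a * U[, k]
    if (k > 1L) w <- w - beta[k - 1L] * U[, k - 1L]
    # full reorthogonalization (two passes) against the stored basis
    Uk <- U[, seq_len(k), drop = FALSE]
    w <- w - Uk %*% crossprod(Uk, w)
    w <- w - Uk %*% crossprod(Uk, w)
    bk <- sqrt(sum(w^2))
    alpha[k] <- a
    y <- solveTridiagE1(alpha, beta, 0)
    res[k] <- bnorm * bk * abs(y[k])
    if (res[k] < tol) { converged <- TRUE; break }
    if (bk < breakdownTol * max(bnorm, 1)) { converged <- TRUE; break }
    if (k >= maxIter) break
    beta[k] <- bk
    if (k + 1L > ncol(U)) U <- cbind(U, matrix(0, n, chunk))
    U[, k + 1L] <- w / bk
  }
  new("LanczosFactorization", bnorm = bnorm,
      U = U[, seq_len(k), drop = FALSE],
      alpha = alpha, beta = beta, resHistory = res,
      converged = converged, steps = k)
}

#' Block Lanczos factorization for multiple seed systems
#'
#' Runs per-column Lanczos recurrences in lockstep, applying the operator
#' to all still-active columns at once (one matrix product per step
#' instead of one vector product per column). The per-column results are
#' mathematically identical to independent \code{\link{lanczosSeed}}
#' calls: each column keeps its own basis, coefficients and residual
#' history, and stops on its own convergence or breakdown. The block is
#' declared converged when every column's residual is below \code{tol}
#' (the max-over-columns criterion).
#'
#' @param A operator as in \code{\link{lanczosSeed}}.
#' @param B matrix of seed columns, all nonzero.
#' @param tol absolute residual 2-norm tolerance per column.
#' @param maxIter maximum steps per column.
#' @return a \code{BlockFactorization}.
#' @export
blockLanczosSeed <- function(A, B, tol = 5e-5, maxIter = NULL) {
  B <- as.matrix(B)
  n <- nrow(B)
  p <- ncol(B)
  if (is.null(maxIter)) maxIter <- min(n, 1000L)
  bnorms <- sqrt(colSums(B^2))
  zero <- which(bnorms == 0)
  if (length(zero))
    stop(sprintf("seed column %d is zero", zero[1L]))
  chunk <- 64L
  st <- lapply(seq_len(p), function(j) {
    U <- matrix(0, n, min(chunk, maxIter))
    U[, 1L] <- B[, j] / bnorms[j]
    list(U = U, alpha = numeric(0), beta = numeric(0), res = numeric(0),
         k = 0L, done = FALSE, converged = FALSE)
  })
  breakdownTol <- 1e-13
  repeat {
    active <- which(!vapply(st, `[[`, logical(1), "done"))
    if (!length(active)) break
    W <- vapply(active, function(j) st[[j]]$U[, st[[j]]$k + 1L], numeric(n))
    if (is.null(dim(W))) W <- matrix(W, nrow = n)
    AW <- applyOperator(A, W)
    for (ii in seq_along(active)) {
      j <- active[ii]
      s <- st[[j]]
      k <- s$k + 1L
      w <- AW[, ii]
      a <- sum(s$U[, k] * w)
      w <- w - a * s$U[, k]
      if (k > 1L) w <- w - s$beta[k - 1L] * s$U[, k - 1L]
      Uk <- s$U[, seq_len(k), drop = FALSE]
      w <- w - Uk %*% crossprod(Uk, w)
      w <- w - Uk %*% crossprod(Uk, w)
      bk <- sqrt(sum(w^2))
      s$alpha[k] <- a
      y <- solveTridiagE1(s$alpha, s$beta, 0)
      s$res[k] <- bnorms[j] * bk * abs(y[k])
      s$k <- k
      if (s$res[k] < tol || bk < breakdownTol * max(bnorms[j], 1)) {
        s$done <- TRUE; s$converged <- TRUE
      } else if (k >= maxIter) {
        s$done <- TRUE; s$converged <- FALSE
      } else {
        s$beta[k] <- bk
        if (k + 1L > ncol(s$U)) s$U <- cbind(s$U, matrix(0, n, chunk))
        s$U[, k + 1L] <- w / bk
      }
      st[[j]] <- s
    }
  }
  facts <- lapply(seq_len(p), function(j) {
    s <- st[[j]]
    new("LanczosFactorization", bnorm = bnorms[j],
        U = s$U[, seq_len(s$k), drop = FALSE],
        alpha = s$alpha, beta = s$beta, resHistory = s$res,
        converged = s$converged, steps = s$k)
  })
  new("BlockFactorization", facts = facts)
}

setMethod("factorizations", "BlockFactorization", function(x) x@facts)

#' Solve a shifted seed system from a stored factorization
#'
#' Returns the conjugate gradient approximate solution
#' \code{x_sigma = ||b|| U (T + sigma I)^{-1} e1} of
#' \code{(A + sigma I) x = b}, using only the stored basis and a
#' tridiagonal solve: O(n k) vector work and zero operator applications.
#' At \code{sigma = 0} this is the seed CG iterate itself.
#'
#' @param fact a \code{LanczosFactorization}.
#' @param sigma nonnegative shift.
#' @return numeric solution vector.
#' @export
lSolve <- function(fact, sigma) {
  stopifnot(is(fact, "LanczosFactorization"))
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("sigma must be a single nonnegative shift")
  y <- solveTridiagE1(fact@alpha, fact@beta, sigma)
  drop(fact@bnorm * (fact@U %*% y))
}

#' Predicted residual norm of a shifted solve
#'
#' Cheap convergence predictor for \code{\link{lSolve}}: the seed
#' residual norm scaled by \code{delta / (delta + sigma)}, where
#' \code{delta} is the last diagonal element of the Jacobi matrix.
#' Equals the seed residual at \code{sigma = 0} and decreases to 0 as
#' \code{sigma} grows; positive shifts never worsen convergence.
#'
#' @param fact a \code{LanczosFactorization}.
#' @param sigma nonnegative shift.
#' @return predicted residual 2-norm.
#' @export
shiftedResidualNorm <- function(fact, sigma) {
  stopifnot(is(fact, "LanczosFactorization"))
  delta <- fact@alpha[fact@steps]
  r0 <- fact@resHistory[fact@steps]
  r0 * delta / (delta + sigma)
}

setMethod("show", "LanczosFactorization", function(object) {
  cat(sprintf(
    "LanczosFactorization: %d steps (n = %d), final residual %.3e%s\n",
    object@steps, nrow(object@U), object@resHistory[object@steps],
    if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "BlockFactorization", function(object) {
  ks <- vapply(object@facts, function(f) f@steps, integer(1))
  conv <- vapply(object@facts, function(f) f@converged, logical(1))
  cat(sprintf(
    "BlockFactorization: %d seed systems, steps %d-%d, %d converged\n",
    length(ks), min(ks), max(ks), sum(conv)))
})
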