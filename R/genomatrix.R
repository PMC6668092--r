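#' Construct a RawGenotypes object
#'
#' @param dosages numeric matrix (samples x variants) with entries in
#'   \{0, 1, 2, NA\}.
#' @param sampleIDs optional character sample identifiers.
#' @param variantIDs optional character variant identifiers.
#' @return a \code{RawGenotypes}.
#' @export
RawGenotypes <- function(dosages, sampleIDs = NULL, variantIDs = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sampleIDs)) sampleIDs <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(variantIDs)) variantIDs <- paste0("V", seq_len(ncol(dosages)))
  new("RawGenotypes", dosages = dosages,
      sampleIDs = as.character(sampleIDs),
      variantIDs = as.character(variantIDs))
}

#' Standardize raw genotypes
#'
#' Mean-imputes missing dosages, drops monomorphic columns and columns
#' with minor allele frequency below \code{mafMin}, and transforms each
#' kept column as \code{(g - 2 p) / sqrt(2 p (1 - p))} with \code{p} the
#' sample allele frequency. The divisor is the binomial variance at the
#' sample frequency (the usual GRM convention), so kept columns have mean
#' zero but not necessarily unit sample variance.
#'
#' @param raw a \code{RawGenotypes}.
#' @param mafMin minor allele frequency cutoff in [0, 0.5); variants with
#'   \code{min(p, 1-p) < mafMin} are dropped. Default 0.01.
#' @return a \code{StandardizedGenotypes}.
#' @export
standardizeGenotypes <- function(raw, mafMin = 0.01) {
  stopifnot(is(raw, "RawGenotypes"))
  if (mafMin < 0 || mafMin >= 0.5)
    stop("mafMin must lie in [0, 0.5)")
  G <- raw@dosages
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- which(is.finite(p) & p > 0 & p < 1 & maf >= mafMin)
  # also drop columns constant after imputation (e.g. all-equal non-missing)
  if (length(keep)) {
    polymorphic <- vapply(keep, function(j) {
      v <- G[, j]
      length(unique(v[!is.na(v)])) > 1L
    }, logical(1))
    keep <- keep[polymorphic]
  }
  if (!length(keep)) stop("no variants remain after filtering")
  Z <- G[, keep, drop = FALSE]
  pk <- p[keep]
  for (jj in seq_along(keep)) {
    col <- Z[, jj]
    col[is.na(col)] <- 2 * pk[jj]        # mean imputation -> exactly 0 centred
    Z[, jj] <- (col - 2 * pk[jj]) / sqrt(2 * pk[jj] * (1 - pk[jj]))
  }
  new("StandardizedGenotypes", Z = Z, keptVariants = as.integer(keep),
      alleleFreqs = as.numeric(pk), sampleIDs = raw@sampleIDs)
}

#' Build the genomic covariance operator H_0
#'
#' Returns the linear operator \code{v -> (1/m) Z Z^T v + tau0 v}, either
#' from an explicit (symmetric) GRM or implicitly from standardized
#' genotypes, in which case the GRM is never formed and each application
#' costs two matrix-vector products. The shift \code{tau0} is applied at
#' application time, so one stored GRM or genotype matrix serves every
#' base shift. When \code{projector} is supplied the GRM part acts as
#' \code{S A S}, giving the projected operator used for quadratic-form
#' and BLUP seed systems.
#'
#' @param source a \code{StandardizedGenotypes} (implicit mode) or a
#'   symmetric GRM matrix (explicit mode).
#' @param tau0 base variance ratio, >= 0.
#' @param projector optional \code{Projector}.
#' @return a \code{GenomicOperator}.
#' @export
makeOperator <- function(source, tau0, projector = NULL) {
  if (length(tau0) != 1L || !is.finite(tau0) || tau0 < 0)
    stop("tau0 must be a single nonnegative number")
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  if (is(source, "StandardizedGenotypes")) {
    new("GenomicOperator", mode = "implicit_genotype", tau0 = tau0,
        n = nrow(source@Z), grm = matrix(0, 0, 0), Z = source@Z,
        projector = projector, counter = counter)
  } else if (is.matrix(source)) {
    if (nrow(source) != ncol(source))
      stop("explicit GRM must be square")
    if (max(abs(source - t(source))) > 1e-8 * max(1, max(abs(source))))
      stop("explicit GRM must be symmetric")
    new("GenomicOperator", mode = "explicit_grm", tau0 = tau0,
        n = nrow(source), grm = source, Z = matrix(0, 0, 0),
        projector = projector, counter = counter)
  } else {
    stop("source must be StandardizedGenotypes or a GRM matrix")
  }
}

#' @describeIn applyOperator apply H_0 (optionally projected) to v.
setMethod("applyOperator", "GenomicOperator", function(op, v, count = TRUE) {
  vec <- is.null(dim(v))
  V <- if (vec) matrix(v, ncol = 1L) else v
  if (nrow(V) != op@n) stop("dimension mismatch")
  if (count) op@counter$n <- op@counter$n + ncol(V)
  W <- if (!is.null(op@projector)) projectOut(op@projector, V) else V
  AW <- if (op@mode == "explicit_grm") {
    op@grm %*% W
  } else {
    m <- ncol(op@Z)
    op@Z %*% crossprod(op@Z, W) / m
  }
  if (!is.null(op@projector)) AW <- projectOut(op@projector, AW)
  out <- AW + op@tau0 * V
  if (vec) drop(out) else out
})

setMethod("operatorApplications", "GenomicOperator", function(op)
  op@counter$n)

setMethod("resetOperatorCounter", "GenomicOperator", function(op) {
  op@counter$n <- 0L
  invisible(op)
})

setMethod("genoMatrix", "StandardizedGenotypes", function(x) x@Z)

#' Build the covariate projector S
#'
#' Economy orthogonal (QR) factorization of the covariate matrix X; the
#' projector applies \code{v - Q_X (Q_X^T v)}. If X is numerically rank
#' deficient the basis is truncated to the detected rank with a warning.
#'
#' @param X covariate matrix (n x c), n > c >= 1; the caller supplies the
#'   intercept column.
#' @return a \code{Projector}.
#' @export
makeProjector <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("X must have at least one column")
  if (nrow(X) <= ncol(X)) stop("need more samples than covariates")
  qrx <- qr(X)
  r <- qrx$rank
  if (r < 1L) stop("covariate matrix has rank zero")
  if (r < ncol(X))
    warning(sprintf("covariate matrix is rank deficient (rank %d < %d); basis truncated",
                    r, ncol(X)))
  Q <- qr.Q(qrx)[, seq_len(r), drop = FALSE]
  new("Projector", Q = Q, rank = as.integer(r),
      rankDeficient = r < ncol(X))
}

#' @describeIn projectOut apply S to a vector or matrix.
setMethod("projectOut", "Projector", function(p, v) {
  vec <- is.null(dim(v))
  V <- if (vec) matrix(v, ncol = 1L) else v
  out <- V - p@Q %*% crossprod(p@Q, V)
  if (vec) drop(out) else out
})

setMethod("show", "RawGenotypes", function(object) {
  cat(sprintf("RawGenotypes: %d samples x %d variants (%d missing calls)\n",
              nrow(object@dosages), ncol(object@dosages),
              sum(is.na(object@dosages))))
})

setMethod("show", "StandardizedGenotypes", function(object) {
  cat(sprintf("StandardizedGenotypes: %d samples x %d kept variants\n",
              nrow(object@Z), ncol(object@Z)))
})

setMethod("show", "GenomicOperator", function(object) {
  cat(sprintf("GenomicOperator (%s): n = %d, tau0 = %g%s; %d applications\n",
              object@mode, object@n, object@tau0,
              if (!is.null(object@projector)) ", projected" else "",
              object@counter$n))
})

setMethod("show", "Projector", function(object) {
  cat(sprintf("Projector onto complement of %d covariate column(s) (n = %d)%s\n",
              object@rank, nrow(object@Q),
              if (object@rankDeficient) " [rank repaired]" else ""))
})
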