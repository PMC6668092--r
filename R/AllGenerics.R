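#' Apply a linear operator to a vector or matrix
#'
#' @param op operator object.
#' @param v numeric vector or matrix conformable with the operator.
#' @param count logical; record the application in the operator's counter
#'   (one count per column).
#' @return numeric vector or matrix of the same shape as \code{v}.
#' @export
setGeneric("applyOperator", function(op, v, count = TRUE)
  standardGeneric("applyOperator"))

#' Project onto the orthogonal complement of the covariate space
#'
#' @param p a \code{Projector}.
#' @param v numeric vector or matrix.
#' @return \code{v - Q_X (Q_X^T v)}.
#' @export
setGeneric("projectOut", function(p, v) standardGeneric("projectOut"))

#' Number of operator applications recorded so far
#' @param op a \code{GenomicOperator}.
#' @return integer count (one per column applied).
#' @export
setGeneric("operatorApplications", function(op)
  standardGeneric("operatorApplications"))

#' Reset the operator application counter
#' @param op a \code{GenomicOperator}.
#' @return the operator, invisibly.
#' @export
setGeneric("resetOperatorCounter", function(op)
  standardGeneric("resetOperatorCounter"))

#' Standardized genotype matrix Z
#' @param x a \code{StandardizedGenotypes} or \code{SyntheticDataset}.
#' @return numeric matrix.
#' @export
setGeneric("genoMatrix", function(x) standardGeneric("genoMatrix"))

#' Estimated heritability
#' @param x a \code{REMLResult} or \code{SyntheticDataset} (true value).
#' @return numeric scalar.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' Variance components
#' @param x a \code{REMLResult} or \code{SyntheticDataset}.
#' @return named numeric vector \code{c(sigmaG2=, sigmaE2=)}.
#' @export
setGeneric("varianceComponents", function(x)
  standardGeneric("varianceComponents"))

#' Per-seed Lanczos factorizations of a block factorization
#' @param x a \code{BlockFactorization}.
#' @return list of \code{LanczosFactorization}.
#' @export
setGeneric("factorizations", function(x) standardGeneric("factorizations"))
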