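#' @import methods
#' @importFrom stats optimize uniroot rbinom rnorm runif sd
NULL

#' Raw allele dosages
#'
#' Hard-called allele dosages for \code{n} samples at \code{m} variants.
#' Entries are 0, 1, 2 or \code{NA} (missing). Rows are samples, columns
#' variants.
#'
#' @slot dosages numeric matrix (n x m) with entries in \{0, 1, 2, NA\}.
#' @slot sampleIDs character vector of length n.
#' @slot variantIDs character vector of length m.
#' @export
setClass("RawGenotypes",
  representation(
    dosages = "matrix",
    sampleIDs = "character",
    variantIDs = "character"
  )
)

setValidity("RawGenotypes", function(object) {
  d <- object@dosages
  if (nrow(d) < 2L) return("need at least 2 samples")
  if (ncol(d) < 1L) return("need at least 1 variant")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    return("non-missing dosages must be 0, 1 or 2")
  if (length(object@sampleIDs) != nrow(d))
    return("sampleIDs length must equal number of rows")
  if (length(object@variantIDs) != ncol(d))
    return("variantIDs length must equal number of columns")
  TRUE
})

#' Standardized genotypes
#'
#' Column-centred, variance-scaled genotype matrix Z. Column j of the raw
#' dosage matrix is transformed as (g - 2 p_j) / sqrt(2 p_j (1 - p_j)) at
#' the sample allele frequency p_j, after mean imputation of missing
#' entries; monomorphic and below-MAF columns are dropped.
#'
#' @slot Z numeric matrix (n x m_kept), columns mean zero.
#' @slot keptVariants integer indices of retained columns in the raw matrix.
#' @slot alleleFreqs numeric vector of sample allele frequencies p_j in (0,1).
#' @slot sampleIDs character vector of sample identifiers.
#' @export
setClass("StandardizedGenotypes",
  representation(
    Z = "matrix",
    keptVariants = "integer",
    alleleFreqs = "numeric",
    sampleIDs = "character"
  )
)

setValidity("StandardizedGenotypes", function(object) {
  if (ncol(object@Z) != length(object@keptVariants))
    return("keptVariants length must equal ncol(Z)")
  if (ncol(object@Z) != length(object@alleleFreqs))
    return("alleleFreqs length must equal ncol(Z)")
  if (any(object@alleleFreqs <= 0 | object@alleleFreqs >= 1))
    return("allele frequencies must lie in (0,1)")
  cm <- colMeans(object@Z)
  if (length(cm) && max(abs(cm)) > 1e-8)
    return("columns of Z must have mean zero")
  TRUE
})

#' Genomic covariance operator
#'
#' The linear map v -> (1/m) Z Z^T v + tau0 v (the base matrix H_0 of the
#' shifted family H_tau = H_0 + sigma I), in one of two modes:
#' \code{"explicit_grm"} stores the dense GRM, \code{"implicit_genotype"}
#' applies Z and Z^T without ever forming the GRM. An optional covariate
#' projector S turns the action into the projected operator
#' v -> (1/m) S Z Z^T S v + tau0 v used for the quadratic-form and BLUP
#' systems. Applications are counted in an environment for cost audits.
#'
#' @slot mode character, "explicit_grm" or "implicit_genotype".
#' @slot tau0 base variance ratio (>= 0) folded in at application time.
#' @slot n problem dimension.
#' @slot grm dense GRM (explicit mode) or 0 x 0 matrix.
#' @slot Z standardized genotype matrix (implicit mode) or 0 x 0 matrix.
#' @slot projector a \code{Projector} or NULL; if set, the GRM part is
#'   sandwiched between projections.
#' @slot counter environment with field \code{n}: number of operator
#'   applications (columns) performed so far.
#' @export
setClass("GenomicOperator",
  representation(
    mode = "character",
    tau0 = "numeric",
    n = "integer",
    grm = "matrix",
    Z = "matrix",
    projector = "ANY",
    counter = "environment"
  )
)

setValidity("GenomicOperator", function(object) {
  if (!object@mode %in% c("explicit_grm", "implicit_genotype"))
    return("mode must be 'explicit_grm' or 'implicit_genotype'")
  if (length(object@tau0) != 1L || object@tau0 < 0)
    return("tau0 must be a single nonnegative number")
  if (object@mode == "explicit_grm" && nrow(object@grm) != object@n)
    return("GRM dimension disagrees with n")
  if (object@mode == "implicit_genotype" && nrow(object@Z) != object@n)
    return("genotype matrix row count disagrees with n")
  TRUE
})

#' Covariate projector
#'
#' Orthogonal projector S: v -> v - Q_X (Q_X^T v) onto the complement of
#' the covariate column space, held implicitly through the economy
#' orthonormal basis Q_X of X.
#'
#' @slot Q orthonormal basis of col(X) (n x r).
#' @slot rank numerical rank r of X (columns of Q).
#' @slot rankDeficient TRUE when r was smaller than ncol(X).
#' @export
setClass("Projector",
  representation(
    Q = "matrix",
    rank = "integer",
    rankDeficient = "logical"
  )
)

setValidity("Projector", function(object) {
  if (ncol(object@Q) != object@rank) return("rank must equal ncol(Q)")
  if (object@rank < 1L) return("projector needs at least one covariate")
  if (nrow(object@Q) <= object@rank) return("need n > number of covariates")
  TRUE
})

#' Lanczos factorization of a seed system
#'
#' The stored output of the Lanczos process on A x = b: orthonormal basis
#' U (with first column b/||b||), tridiagonal Jacobi coefficients alpha
#' (diagonal) and beta (off-diagonal), the seed norm, and the conjugate
#' gradient residual-norm history. This object supports O(n k) solution
#' of every shifted system (A + sigma I) x = b via \code{lSolve} as well
#' as Gaussian quadrature for spectral functions of A.
#'
#' @slot bnorm seed 2-norm ||b||.
#' @slot U orthonormal Krylov basis (n x k).
#' @slot alpha diagonal Jacobi coefficients (length k).
#' @slot beta off-diagonal Jacobi coefficients (length k-1).
#' @slot resHistory CG residual norm of A x = b after each step.
#' @slot converged TRUE if the residual tolerance was met.
#' @slot steps number of Lanczos steps k.
#' @export
setClass("LanczosFactorization",
  representation(
    bnorm = "numeric",
    U = "matrix",
    alpha = "numeric",
    beta = "numeric",
    resHistory = "numeric",
    converged = "logical",
    steps = "integer"
  )
)

setValidity("LanczosFactorization", function(object) {
  k <- object@steps
  if (k < 1L) return("factorization must have at least one step")
  if (ncol(object@U) != k) return("U must have `steps` columns")
  if (length(object@alpha) != k) return("alpha must have length `steps`")
  if (length(object@beta) != max(k - 1L, 0L))
    return("beta must have length steps - 1")
  TRUE
})

#' Block Lanczos factorization
#'
#' One \code{LanczosFactorization} per right-hand-side column of B, all
#' built on the same operator with a shared step schedule.
#'
#' @slot facts list of \code{LanczosFactorization}, one per column.
#' @export
setClass("BlockFactorization", representation(facts = "list"))

setValidity("BlockFactorization", function(object) {
  ok <- vapply(object@facts, function(f) is(f, "LanczosFactorization"),
               logical(1))
  if (!all(ok)) return("facts must all be LanczosFactorization objects")
  TRUE
})

#' Rademacher probe set
#'
#' \code{nRand} i.i.d. normalized Rademacher vectors (entries +-1/sqrt(n),
#' unit 2-norm) for Hutchinson-type stochastic trace estimation.
#'
#' @slot V matrix of probes (n x nRand).
#' @slot seed integer seed the probes were drawn from.
#' @export
setClass("ProbeSet", representation(V = "matrix", seed = "numeric"))

setValidity("ProbeSet", function(object) {
  n <- nrow(object@V)
  if (n < 1L || ncol(object@V) < 1L) return("probe matrix must be nonempty")
  vals <- sort(unique(as.vector(object@V)))
  if (length(vals) != 2L || max(abs(abs(vals) - 1 / sqrt(n))) > 1e-12)
    return("probe entries must be +-1/sqrt(n)")
  TRUE
})

#' Gaussian quadrature rules from Jacobi matrices
#'
#' Per probe vector: nodes (eigenvalues of the tridiagonal Jacobi matrix)
#' and weights (squared first components of its eigenvectors) of the
#' Gaussian quadrature for the spectral measure of (A, v). Shifting A by
#' sigma I shifts every node by sigma and leaves the weights unchanged,
#' which is what makes the whole log-determinant family cheap.
#'
#' @slot nodes list of numeric vectors, one per probe.
#' @slot weights list of numeric vectors, summing to 1 per probe.
#' @slot n operator dimension the probes act on.
#' @export
setClass("QuadratureRule",
  representation(nodes = "list", weights = "list", n = "integer")
)

setValidity("QuadratureRule", function(object) {
  if (length(object@nodes) != length(object@weights))
    return("nodes and weights must have equal length")
  for (k in seq_along(object@weights)) {
    w <- object@weights[[k]]
    if (abs(sum(w) - 1) > 1e-8) return("weights must sum to 1 per probe")
    if (length(w) != length(object@nodes[[k]]))
      return("per-probe nodes and weights must have equal length")
  }
  TRUE
})

#' REML fit result
#'
#' Variance-component estimates and diagnostics from \code{fitSLDF} or
#' \code{fitFOMC} (or the dense oracle). The profiled log-likelihood is
#' reported up to an additive constant.
#'
#' @slot h2 estimated heritability in [h2_min, h2_max].
#' @slot sigmaG2 genetic variance component (phenotype-variance units).
#' @slot sigmaE2 residual variance component.
#' @slot logLik profiled REML log-likelihood at the optimum (up to constant).
#' @slot nEval criterion / root-statistic evaluation count.
#' @slot lanczosIters Lanczos step counts of the seed factorizations.
#' @slot algorithm "sldf", "fomc" or "dense".
#' @slot boundary TRUE when the optimum sits on the parameter boundary.
#' @slot warnings character vector of accumulated warnings.
#' @export
setClass("REMLResult",
  representation(
    h2 = "numeric",
    sigmaG2 = "numeric",
    sigmaE2 = "numeric",
    logLik = "numeric",
    nEval = "integer",
    lanczosIters = "integer",
    algorithm = "character",
    boundary = "logical",
    warnings = "character"
  )
)

setValidity("REMLResult", function(object) {
  if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
    return("variance components must be nonnegative")
  h2 <- object@sigmaG2 / (object@sigmaG2 + object@sigmaE2)
  if (abs(h2 - object@h2) > 1e-10)
    return("h2 must equal sigmaG2/(sigmaG2+sigmaE2)")
  TRUE
})

#' Synthetic dataset under the two-component model
#'
#' Genotypes, covariates, phenotype and the latent draws that generated
#' it, with the true variance components, for recovery tests.
#'
#' @slot raw \code{RawGenotypes}.
#' @slot geno \code{StandardizedGenotypes} derived from \code{raw}.
#' @slot X covariate matrix including intercept.
#' @slot beta fixed effects used.
#' @slot y phenotype vector.
#' @slot u latent per-SNP effects (length m_kept).
#' @slot e latent residuals (length n).
#' @slot h2 true heritability.
#' @slot sigmaG2 true genetic variance.
#' @slot sigmaE2 true residual variance.
#' @slot seeds named numeric vector of the seeds used.
#' @export
setClass("SyntheticDataset",
  representation(
    raw = "RawGenotypes",
    geno = "StandardizedGenotypes",
    X = "matrix",
    beta = "numeric",
    y = "numeric",
    u = "numeric",
    e = "numeric",
    h2 = "numeric",
    sigmaG2 = "numeric",
    sigmaE2 = "numeric",
    seeds = "numeric"
  )
)
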