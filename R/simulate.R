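#' Simulate hard-called genotypes
#'
#' Allele frequencies drawn uniformly on [mafLow, mafHigh]; dosages are
#' i.i.d. Binomial(2, p_j) across samples. No linkage disequilibrium and
#' no relatedness by construction.
#'
#' @param n samples (>= 2); \code{m} variants.
#' @param m number of variants.
#' @param mafLow,mafHigh allele frequency range, 0 < mafLow <= mafHigh < 0.5.
#' @param seed integer seed.
#' @return a \code{RawGenotypes}.
#' @export
simulateGenotypes <- function(n, m, mafLow = 0.05, mafHigh = 0.45,
                              seed = 1L) {
  if (!(mafLow > 0 && mafLow <= mafHigh && mafHigh < 0.5))
    stop("need 0 < mafLow <= mafHigh < 0.5")
  withSeed(seed, {
    p <- runif(m, mafLow, mafHigh)
    G <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    RawGenotypes(G)
  })
}

#' Simulate a phenotype under the two-component model
#'
#' \code{y = X beta + (1/sqrt(m)) Z u + e} with
#' \code{u ~ N(0, sigma_g^2 I_m)}, \code{e ~ N(0, sigma_e^2 I_n)},
#' \code{sigma_g^2 = h2 * varTotal} and \code{sigma_e^2 = (1-h2) * varTotal}.
#' The latent draws are returned for BLUP-accuracy tests.
#'
#' @param Z standardized genotype matrix or \code{StandardizedGenotypes}.
#' @param X covariate matrix including intercept.
#' @param beta fixed effects (length ncol(X)).
#' @param h2 true heritability in [0, 1].
#' @param varTotal total phenotypic variance (default 1).
#' @param seed integer seed.
#' @return list with \code{y}, \code{u}, \code{e}, \code{sigmaG2},
#'   \code{sigmaE2}.
#' @export
simulatePhenotype <- function(Z, X, beta = NULL, h2 = 0.5, varTotal = 1,
                              seed = 1L) {
  if (is(Z, "StandardizedGenotypes")) Z <- Z@Z
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  X <- as.matrix(X)
  if (is.null(beta)) beta <- rep(0, ncol(X))
  n <- nrow(Z)
  m <- ncol(Z)
  sigmaG2 <- h2 * varTotal
  sigmaE2 <- (1 - h2) * varTotal
  withSeed(seed, {
    u <- rnorm(m, sd = sqrt(sigmaG2))
    e <- rnorm(n, sd = sqrt(sigmaE2))
    y <- drop(X %*% beta) + drop(Z %*% u) / sqrt(m) + e
    list(y = y, u = u, e = e, sigmaG2 = sigmaG2, sigmaE2 = sigmaE2)
  })
}

#' Simulate a complete dataset with known generative parameters
#'
#' Convenience wrapper: genotypes, standardization, covariates (intercept
#' plus optional standard-normal columns) and phenotype, with all latent
#' draws and seeds recorded for exact reproduction.
#'
#' @param n samples; \code{m} variants.
#' @param m number of variants.
#' @param h2 true heritability.
#' @param nCovar number of non-intercept covariates (default 0).
#' @param beta fixed effects (default zero except nothing; intercept
#'   effect 0).
#' @param varTotal total phenotypic variance.
#' @param mafLow,mafHigh allele-frequency range for the genotypes.
#' @param mafMin standardization MAF cutoff.
#' @param seed integer base seed; genotype, covariate and phenotype
#'   streams are derived from it.
#' @return a \code{SyntheticDataset}.
#' @export
simulateDataset <- function(n, m, h2 = 0.5, nCovar = 0L, beta = NULL,
                            varTotal = 1, mafLow = 0.05, mafHigh = 0.45,
                            mafMin = 0.01, seed = 1L) {
  seed <- as.integer(seed)
  genoSeed <- seed
  covarSeed <- (seed + 104729L) %% .Machine$integer.max
  phenoSeed <- (seed + 1299709L) %% .Machine$integer.max
  raw <- simulateGenotypes(n, m, mafLow, mafHigh, genoSeed)
  geno <- standardizeGenotypes(raw, mafMin)
  X <- cbind(intercept = rep(1, n))
  if (nCovar > 0L) {
    Xc <- withSeed(covarSeed, matrix(rnorm(n * nCovar), n, nCovar))
    colnames(Xc) <- paste0("covar", seq_len(nCovar))
    X <- cbind(X, Xc)
  }
  if (is.null(beta)) beta <- rep(0, ncol(X))
  ph <- simulatePhenotype(geno, X, beta, h2, varTotal, phenoSeed)
  new("SyntheticDataset", raw = raw, geno = geno, X = X,
      beta = as.numeric(beta), y = ph$y, u = ph$u, e = ph$e,
      h2 = h2, sigmaG2 = ph$sigmaG2, sigmaE2 = ph$sigmaE2,
      seeds = c(genotypes = genoSeed, covariates = covarSeed,
                phenotype = phenoSeed))
}

setMethod("genoMatrix", "SyntheticDataset", function(x) x@geno@Z)
setMethod("heritability", "SyntheticDataset", function(x) x@h2)
setMethod("varianceComponents", "SyntheticDataset", function(x)
  c(sigmaG2 = x@sigmaG2, sigmaE2 = x@sigmaE2))

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d samples x %d variants (%d kept), true h2 = %.3f\n",
    nrow(object@raw@dosages), ncol(object@raw@dosages),
    ncol(object@geno@Z), object@h2))
})

#' Compute the dense GRM of a standardized genotype matrix
#'
#' @param geno \code{StandardizedGenotypes} or numeric matrix Z.
#' @return dense GRM \code{(1/m) Z Zt}.
#' @export
computeGRM <- function(geno) {
  Z <- if (is(geno, "StandardizedGenotypes")) geno@Z else as.matrix(geno)
  tcrossprod(Z) / ncol(Z)
}
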