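Package: LanczosREML
Title: Stochastic Lanczos REML Estimation of Genomic Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Residual maximum likelihood (REML) estimation of the two
    variance component genomic linear mixed model via Krylov subspace
    shift invariance. Implements the stochastic Lanczos derivative-free
    REML algorithm (SLDF-REML) and the Lanczos first-order Monte Carlo
    REML algorithm (L-FOMC-REML): a single round of (block) Lanczos
    factorizations at a base variance ratio yields O(n) evaluation of
    the profiled REML criterion, shifted-system solves, stochastic
    Lanczos quadrature log-determinant estimates, and BLUPs of SNP
    effects for every parameter value visited by the optimizer. Includes
    a dense spectral-decomposition REML oracle, a synthetic-data
    generator for the model, and readers and writers for PLINK1 binary
    genotypes and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
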