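test_that("Monte Carlo samples live in the range of the projector", {
  geno <- standardizeGenotypes(simulateGenotypes(40, 60, seed = 3), 0)
  proj <- makeProjector(cbind(1, rnorm(40)))
  s <- drawMCPhenotypes(geno, proj, nRand = 6, seed = 4)
  for (tau in c(0.5, 1, 3)) {
    Y <- mcPhenotypes(s, tau)
    expect_lt(max(abs(projectOut(proj, Y) - Y)), 1e-12)
  }
  # determinism
  s2 <- drawMCPhenotypes(geno, proj, nRand = 6, seed = 4)
  expect_identical(s$G, s2$G)
  expect_identical(s$E, s2$E)
})

test_that("residual parts have covariance S", {
  n <- 20
  set.seed(5)
  X <- cbind(1, rnorm(n))
  proj <- makeProjector(X)
  geno <- standardizeGenotypes(simulateGenotypes(n, 30, seed = 6), 0)
  s <- drawMCPhenotypes(geno, proj, nRand = 5000, seed = 7)
  S <- diag(n) - tcrossprod(proj@Q)
  Chat <- tcrossprod(s$E) / 5000
  # entrywise MC standard error of a covariance estimate is about
  # sqrt((S_ii S_jj + S_ij^2)/N); bound with the largest diagonal
  # the check is a max over 400 entries, so allow the expected extreme
  # of that many 3-sigma comparisons rather than a single one
  se <- sqrt(2 * max(diag(S))^2 / 5000)
  expect_lt(max(abs(Chat - S)), 4.5 * se)
})

test_that("BLUPs match dense evaluation and shrink correctly", {
  n <- 100; m <- 150
  d <- simulateDataset(n, m, h2 = 0.5, nCovar = 1L, seed = 31)
  Z <- genoMatrix(d)
  proj <- makeProjector(d@X)
  Sy <- projectOut(proj, d@y)
  space <- parameterSpace(0.05, 0.95)
  S <- diag(n) - tcrossprod(proj@Q)
  Hacc <- S %*% tcrossprod(Z) %*% S / ncol(Z)
  fact <- lanczosSeed(makeOperator(d@geno, space$tau0, projector = proj),
                      Sy, tol = 1e-11)
  for (tau in c(0.4, 1, 2.5)) {
    sigma <- tau - space$tau0
    bl <- blup(fact, sigma, tau, Z, proj)
    xd <- solve(Hacc + tau * diag(n), Sy)
    uDense <- drop(crossprod(Z, S %*% xd)) / sqrt(ncol(Z))
    eDense <- tau * xd
    expect_lt(sqrt(sum((bl$u - uDense)^2)) / sqrt(sum(uDense^2)), 1e-6)
    expect_lt(sqrt(sum((bl$e - eDense)^2)) / sqrt(sum(eDense^2)), 1e-6)
  }
  # ridge limit: tau -> infinity kills u and pushes e to Sy
  big <- blup(fact, 1e8 - space$tau0, 1e8, Z, proj)
  expect_lt(sqrt(sum(big$u^2)), 1e-5)
  expect_lt(sqrt(sum((big$e - Sy)^2)) / sqrt(sum(Sy^2)), 1e-4)
  # a Zt-product counter increments once per call
  cnt <- new.env(); cnt$n <- 0L
  blup(fact, 0, space$tau0, Z, proj, ztCounter = cnt)
  expect_identical(cnt$n, 1L)
})

test_that("BLUPs vanish for a phenotype in the covariate space", {
  n <- 50
  d <- simulateDataset(n, 80, h2 = 0.5, nCovar = 1L, seed = 41)
  proj <- makeProjector(d@X)
  yIn <- drop(d@X %*% c(1, 2))
  expect_lt(sqrt(sum(projectOut(proj, yIn)^2)), 1e-10)
  # the seed system itself is degenerate, so the precondition is caught
  expect_error(fomcState(yIn, d@X, d@geno), "covariate column space")
})

test_that("Monte Carlo BLUP norms are unbiased for their analytic traces", {
  n <- 60; m <- 90
  d <- simulateDataset(n, m, h2 = 0.5, nCovar = 1L, seed = 51)
  Z <- genoMatrix(d)
  proj <- makeProjector(d@X)
  S <- diag(n) - tcrossprod(proj@Q)
  Hacc <- S %*% tcrossprod(Z) %*% S / m
  tau <- 0.8
  Ht <- Hacc + tau * diag(n)
  HtInv <- solve(Ht)
  # Cov(y_check(tau)) restricted to range(S) is Hacc + tau S
  Cov <- Hacc + tau * S
  B <- crossprod(Z, S %*% HtInv) / sqrt(m)
  exactUU <- sum(diag(B %*% Cov %*% t(B)))
  exactEE <- tau^2 * sum(diag(HtInv %*% Cov %*% HtInv))
  space <- parameterSpace(0.05, 0.95)
  sigma <- tau - space$tau0
  reps <- vapply(1:40, function(s) {
    st <- fomcState(d@y, d@X, d@geno, space, nRand = 10,
                    lanczosTol = 1e-10, seed = s)
    Xg <- vapply(st$gFacts, function(f) lSolve(f, sigma), numeric(n))
    Xe <- vapply(st$eFacts, function(f) lSolve(f, sigma), numeric(n))
    Xmc <- Xg + sqrt(tau) * Xe
    U <- crossprod(Z, projectOut(proj, Xmc)) / sqrt(m)
    c(mean(colSums(U^2)), tau^2 * mean(colSums(Xmc^2)))
  }, numeric(2))
  seUU <- sd(reps[1, ]) / sqrt(ncol(reps))
  seEE <- sd(reps[2, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - exactUU), 3 * seUU)
  expect_lt(abs(mean(reps[2, ]) - exactEE), 3 * seEE)
})

test_that("root statistic is near zero at the dense-oracle optimum", {
  fix <- smallDataset(400, 800, h2 = 0.5, nCovar = 1L, seed = 61)
  d <- fix$d
  oracle <- denseREML(d@y, d@X, fix$grm)
  fr <- vapply(1:6, function(s) {
    st <- fomcState(d@y, d@X, d@geno, nRand = 40, seed = s)
    fRootStatistic(st, oracle$h2)
  }, numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr)), 3 * se)
})

test_that("root statistic is monotone in tau and brackets its root", {
  fix <- smallDataset(300, 600, h2 = 0.5, nCovar = 1L, seed = 71)
  d <- fix$d
  st <- fomcState(d@y, d@X, d@geno, nRand = 20, seed = 3)
  h2grid <- seq(0.9, 0.1, by = -0.2)  # tau increasing
  vals <- vapply(h2grid, function(h) fRootStatistic(st, h), numeric(1))
  # observed-vs-expected BLUP ratios cross exactly once: monotone over
  # the grid with a sign change at the estimate
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  expect_lt(min(vals) * max(vals), 0)
})

test_that("fitFOMC agrees with the oracle and with fitSLDF, reproducibly", {
  fix <- smallDataset(500, 1000, h2 = 0.5, nCovar = 1L, seed = 81)
  d <- fix$d
  oracle <- denseREML(d@y, d@X, fix$grm)
  ff <- fitFOMC(d@y, d@X, d@geno, nRand = 30, seed = 5)
  fs <- fitSLDF(d@y, d@X, d@geno, nRand = 30, seed = 5)
  expect_lt(abs(ff@h2 - oracle$h2), 0.03)
  expect_lt(abs(ff@h2 - fs@h2), 0.04)
  # bitwise reproducibility with fixed seeds
  ff2 <- fitFOMC(d@y, d@X, d@geno, nRand = 30, seed = 5)
  expect_identical(ff@h2, ff2@h2)
  # GRM input is rejected: the genotype matrix is required
  expect_error(fitFOMC(d@y, d@X, fix$grm), "genotype matrix")
})

test_that("FOMC iterations apply no operator and one Zt-product per BLUP", {
  fix <- smallDataset(200, 400, h2 = 0.5, nCovar = 1L, seed = 91)
  d <- fix$d
  out <- fitFOMC(d@y, d@X, d@geno, nRand = 8, seed = 7, returnState = TRUE)
  st <- out$state
  opsBefore <- operatorApplications(st$opProj)
  ztBefore <- st$ztCounter$n
  fRootStatistic(st, 0.4)
  expect_identical(operatorApplications(st$opProj), opsBefore)
  # one product per BLUP: observed phenotype + nRand MC phenotypes
  expect_identical(st$ztCounter$n - ztBefore, 8L + 1L)
})
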