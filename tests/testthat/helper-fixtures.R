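# Shared fixtures: all randomness goes through fixed seeds so the suite
# is reproducible run to run.

randomSPD <- function(n, seed, ridge = 0.5) {
  set.seed(seed)
  W <- matrix(rnorm(n * n), n, n)
  crossprod(W) / n + ridge * diag(n)
}

# small dataset with intercept + covariates, returned with its GRM
smallDataset <- function(n, m, h2 = 0.5, nCovar = 2L, seed = 1L) {
  d <- simulateDataset(n, m, h2 = h2, nCovar = nCovar, seed = seed)
  list(d = d, grm = computeGRM(d@geno))
}

# per-probe SLQ estimates at shift sigma; their spread gives the
# empirical Monte Carlo standard error of the trace estimate
slqPerProbe <- function(rules, sigma) {
  vapply(seq_along(rules@nodes), function(k)
    rules@n * sum(rules@weights[[k]] * log(rules@nodes[[k]] + sigma)),
    numeric(1))
}
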