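---
title: "Stochastic Lanczos REML for genomic variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Lanczos REML for genomic variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LanczosREML)
```

## The model

LanczosREML estimates the two variance component genomic linear mixed
model used throughout GWAS practice:

$$y = X\beta + \tfrac{1}{\sqrt m} Z u + e, \qquad
  u \sim \mathcal N(0, \sigma_g^2 I_m), \quad
  e \sim \mathcal N(0, \sigma_e^2 I_n),$$

where $Z$ is the $n \times m$ matrix of standardized genotypes and $X$
holds $c \ll n$ covariates including an intercept. The marginal
covariance of $y$ is $\sigma_g^2 H_\tau$ with

$$H_\tau = \tfrac1m Z Z^\top + \tau I_n, \qquad \tau = \sigma_e^2/\sigma_g^2,$$

and $\tfrac1m Z Z^\top$ is the genomic relatedness matrix (GRM).
Restricted maximum likelihood (REML) works with the data projected
orthogonally to the covariates; after profiling out $\sigma_g^2$
analytically, a single free parameter remains, which we parametrize by
the heritability $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2) = 1/(1+\tau)$.
The profiled criterion maximized by the package is, up to an additive
constant,

$$\ell(h^2) = -(n-c)\,\ln\bigl(y^\top P_\tau y\bigr)
  - \ln\det\bigl(K^\top H_\tau K\bigr),$$

where $K$ is an orthonormal basis of the complement of
$\mathrm{col}(X)$ and $P_\tau = K (K^\top H_\tau K)^{-1} K^\top$. We use
the profiled form because the stationarity conditions determine
$\hat\sigma_g^2(\tau) = y^\top P_\tau y/(n-c)$ exactly; substituting
them into the restricted likelihood removes the nuisance scale and
leaves a one-dimensional, bounded optimization problem. Correctness is
certified against a dense spectral-decomposition implementation of the
same criterion (`denseREML()`), by comparing criterion *differences*
(the additive constant, which includes $\ln\det(X^\top X)$, cancels).

## Why one round of Lanczos work suffices

Krylov subspaces are shift invariant:
$\mathcal K_k(A, b) = \mathcal K_k(A + \sigma I, b)$. The package
anchors the operator at the smallest variance ratio in the search range,
$\tau_0 = (1-h^2_{\max})/h^2_{\max}$, so every parameter value visited
corresponds to a nonnegative shift $\sigma = \tau - \tau_0$ of
$H_0 = H_{\tau_0}$, and the shifted operator is never worse conditioned
than $H_0$. Running the Lanczos process once per seed vector (with the
basis stored) then gives, for *every* shift:

* the conjugate-gradient solution of $(H_0+\sigma I)x = b$ as
  $x_\sigma = \lVert b\rVert\, U (T + \sigma I)^{-1} e_1$ — an $O(nk)$
  tridiagonal solve with zero further operator applications
  (`lSolve()`);
* a Gaussian quadrature for spectral functions whose nodes shift with
  $\sigma$ while the weights stay fixed, so the stochastic Lanczos
  quadrature (SLQ) estimate of $\ln\det(H_0+\sigma I)$ is pure vector
  arithmetic (`slqLogDet()`).

The three criterion ingredients are produced by three groups of seed
systems, built once per fit:

1. **Quadratic form.** Writing $S = I - Q_X Q_X^\top$ for the covariate
   projector, $y^\top P_\tau y = y^\top S (S H_0 S + \sigma I)^{-1} S y$
   (the pseudo-inverse of the rank-deficient projected matrix agrees
   with this resolvent on the range of $S$). One factorization of the
   projected operator with seed $Sy$ covers all shifts.
2. **Covariate log-determinant.**
   $\ln\det(K^\top H_\tau K) = \ln\det H_\tau +
   \ln\det(X^\top H_\tau^{-1} X) - \ln\det(X^\top X)$. The middle term
   needs the $c$ solves $H_\tau^{-1} x_j$, taken from a block
   factorization with the covariate columns as seeds; the last term is
   constant and dropped.
3. **Operator log-determinant.** $\ln\det H_\tau$ is estimated by SLQ
   with `nRand` normalized Rademacher probes on the *unprojected* $H_0$
   (matching the three-term identity above, which is stated for the
   unprojected operator).

`fitSLDF()` assembles these and maximizes $\ell(h^2)$ by Brent's method
(base R `optimize()`). `fitFOMC()` instead solves the first-order
condition: at the REML optimum the observed squared norms of the BLUPs

$$\tilde u(\tau) = m^{-1/2} Z^\top S \acute H_\tau^{-1} S y, \qquad
  \tilde e(\tau) = \tau\, \acute H_\tau^{-1} S y, \qquad
  \acute H_\tau = \tfrac1m S Z Z^\top S + \tau I,$$

equal their model expectations. The expectations are approximated by
Monte Carlo: synthetic projected phenotypes drawn from the model at the
*current* $\tau$, pushed through the same BLUP formulas. The root of

$$f_r(\tau) = \ln\frac{\tilde u^\top \tilde u}{\tilde e^\top \tilde e}
  - \ln\frac{\mathbb E_{\mathrm{MC}}[\tilde u^\top \tilde u]}
            {\mathbb E_{\mathrm{MC}}[\tilde e^\top \tilde e]}$$

is found by bracketed Brent root-finding on the $h^2$ scale. The overall
variance scale $\sigma_g^2$ cancels in both ratios, so the Monte Carlo
samples can be drawn at unit genetic scale.

### Monte Carlo phenotypes must track the variance ratio

A design point that the implementation forced: the Monte Carlo
phenotype is
$\check y_k(\tau) = m^{-1/2} S Z \check u_k + \sqrt\tau\, \check e_k$
with $\check u_k \sim \mathcal N(0, I_m)$ and
$\check e_k \sim \mathcal N(0, S)$ — the residual part is *rescaled by
$\sqrt\tau$ at every evaluation*. If instead the samples are frozen at
unit residual scale, their covariance is the model covariance at
$\tau = 1$ regardless of the $\tau$ being evaluated, the Monte Carlo
expectations are taken under the wrong law, and $f_r$ loses its root at
the REML optimum (we verified both the algebra, via the covariance
$\mathrm{Cov}(\check y(\tau)) = \tfrac1m S Z Z^\top S + \tau S =
\acute H_\tau$ on the range of $S$, and the failure empirically).
Because $\check y_k(\tau)$ is linear in the two parts, each sample
contributes *two* seed systems (genetic and residual), giving
$2\,n_{\mathrm{rand}}+1$ factorizations in the overhead round; the
shifted solves recombine as
$x_k(\tau) = x^{(g)}_k(\sigma) + \sqrt\tau\, x^{(e)}_k(\sigma)$.
With this construction $f_r$ is empirically monotone increasing in
$\tau$ on our synthetic instances (negative below the optimum, positive
above); the bracket-based root finder does not rely on either direction.

### Quadrature weights

The Gaussian quadrature weight for node $\ell$ of a Jacobi matrix
$T = W D W^\top$ is the *squared* first eigenvector component
$\omega_\ell = (e_1^\top W)_\ell^2$. This is the standard
Golub–Meurant construction implied by the Riemann–Stieltjes form of
$v^\top f(A) v$; the unsquared variant fails the $A = cI$ sanity check
(where the estimate must be exact), which the test suite enforces.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `nRand` | 15 | count | SLQ probes (SLDF) / MC samples (FOMC). Controls the stochastic error of the log-determinant / expectation estimates; 15 matches standard practice for this estimator family. |
| `lanczosTol` | 5e-5 | residual 2-norm | absolute CG residual at which a seed factorization stops. |
| `optTol` | 1e-5 | $h^2$ | absolute Brent tolerance of the optimizer / root finder. |
| `h2Min`, `h2Max` | 0.01, 0.99 | $h^2$ | search interval; `h2Max` fixes the base shift $\tau_0$ and hence the conditioning of all seed systems. The interval keeps $\tau$ finite and every shift nonnegative. |
| `mafMin` | 0.01 | allele frequency | variants below this minor allele frequency are dropped before standardization. |
| `maxIter` | `min(n, 1000)` | count | Lanczos iteration cap; hitting it flags (but does not abort) the fit. |

Standardization divides centred dosages by $\sqrt{2p(1-p)}$ at the
sample allele frequency — the binomial variance, i.e. the standard GRM
convention — rather than the sample standard deviation; missing dosages
are mean-imputed, which makes their standardized value exactly zero.
The GRM divisor is the number of variants kept after filtering.

## Numerical choices

* **Full reorthogonalization.** Stored bases are reorthogonalized twice
  per step. The basis must be kept anyway for the $O(nk)$ shifted
  solves, and quadrature nodes degrade badly under loss of
  orthogonality, so the extra $O(nk^2)$ is accepted.
* **Breakdown** ($\beta_k < 10^{-13}\lVert b\rVert$) is happy
  termination: an invariant subspace has been captured and the solves
  and quadrature are exact on it.
* **Residual recovery.** The CG residual of $Ax=b$ after $k$ steps is
  read off the tridiagonal recurrence as
  $\lVert b\rVert\,\beta_k\,\lvert e_k^\top T_k^{-1}e_1\rvert$, so
  monitoring costs no operator work. The shifted-residual predictor
  $\delta_k/(\delta_k+\sigma)\cdot r_k$ is exposed as a cheap
  *conservative* convergence indicator: positive shifts only improve
  convergence, and tests assert the $\sigma = 0$ identity and the
  non-worsening inequality rather than exact equality, which does not
  hold in general.
* **Shifted tridiagonal systems** are solved by the Thomas algorithm
  without pivoting ($T + \sigma I$ is positive definite for
  $\sigma \ge 0$); a vanishing pivot raises an error rather than
  returning garbage.
* **Boundary optima** are reported with a flag, never clamped silently;
  a criterion surface that is flat across the whole interval (e.g. an
  identity GRM, where $\tau$ and $\sigma_g^2$ are confounded) raises an
  "unidentifiable" warning.
* **Seeds.** Every random component (probes, MC samples, simulated
  data) is drawn under an explicitly passed seed through a private RNG
  state, so runs are bitwise reproducible and the caller's RNG stream
  is untouched. Probe and MC streams are seeded independently.

## The synthetic-data generator

`simulateGenotypes()` draws allele frequencies uniformly on
[0.05, 0.45] and dosages i.i.d. Binomial(2, $p_j$): unlinked variants
and unrelated individuals. `simulatePhenotype()` then follows the
generative model exactly, with total variance 1 by default and all-zero
fixed effects unless specified. This emulates the covariance *structure*
the estimators operate on, which is what the algorithms are sensitive
to; it does not emulate linkage disequilibrium, population
stratification, relatedness, or MAF-dependent effect-size coupling.
Passing tests therefore certify the numerics of the estimators under
the stated model, not robustness to model misspecification in real
cohorts (the model's own assumption set applies there).

## Verification strategy and problem sizes

The trust chain is: closed forms validate the dense oracle; the dense
oracle validates every stochastic component. The test suite checks,
among others: shifted Lanczos solves against dense solves (50 systems,
$n = 150$, relative error $\le 10^{-6}$); SLQ estimates within 3
empirical Monte Carlo standard errors of exact log-determinants
($n = 200$, 100 probes); the projected quadratic form against an
explicit-basis dense evaluation ($n = 120$, 20 instances, 5 shifts,
relative error $\le 10^{-6}$); criterion differences against the dense
profiled likelihood ($n = 300$, 10 probe re-seeds); replicate-averaged
estimator agreement with the oracle ($n = 1000$, $m = 2000$, 10
replicates, mean
$|\hat h^2_{\mathrm{SLDF}} - \hat h^2_{\mathrm{dense}}| \le 0.01$ and
FOMC within 0.02 — the per-replicate deviation is mean-zero probe
noise, so the bound applies to the replicate average); mean recovery of $h^2 \in \{0.2, 0.5, 0.8\}$ over 20
replicates at $n = 800$; and the structural contract that
post-overhead evaluations perform zero operator applications (SLDF) and
exactly one $Z^\top$-product per BLUP (FOMC), verified with an
instrumented operator. Unit tests use smaller instances of the same
checks; the generator-plus-oracle recovery certification runs at
$n = 400$, $m = 800$ with 8 replicates per heritability level.

## Known limitations

* Two variance components only; the shift-invariance trick does not
  extend to three or more simultaneous covariance structures.
* No standard errors for $\hat h^2$: the algorithms are derivative-free
  or first-order and never form an information matrix.
* Dense in-memory genotypes/GRM; no out-of-core access, dosage data, or
  LD-weighted GRMs.
* The dense oracle is limited to $n \le 3000$ by design.
* Implicit preconditioning is available only in the usual indirect way:
  append leading singular vectors of $Z$ to the covariates; computing
  them is the caller's concern.
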