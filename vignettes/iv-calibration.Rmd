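---
title: "Instrumental-variable calibration for finite-population totals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Instrumental-variable calibration for finite-population totals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivcalib)
```

## The estimation problem

We want the total $t_y = \sum_{k \in U} y_k$ of a study variable over a finite
universe $U$ of $N$ units, from a probability sample $s$ of size $n$. Each unit
carries a vector of $p$ auxiliary variables $x_k$ whose population totals
$t_x = \sum_U x_k$ are known (from a census, register or administrative
source). Throughout, samples are drawn by simple random sampling without
replacement (SRSWOR), so $\pi_k = n/N$ and the design weight is $d_k = N/n$.

The baseline is the Horvitz–Thompson (HT) estimator
$\hat t_{y\pi} = \sum_s d_k y_k$, which ignores the auxiliaries. Calibration
adjusts the design weights as little as possible (in a chosen distance)
subject to $\sum_s w_k x_k = t_x$; with the chi-square distance
$\sum_s (w_k - d_k)^2 / (d_k q_k)$ the solution is
$w_k = d_k (1 + q_k x_k^T \lambda)$,
$\lambda = (\sum_s d_k q_k x_k x_k^T)^{-1}(t_x - \hat t_{x\pi})$, and the
resulting estimator is the generalized regression (GREG) estimator
$$\hat t_{GREG} = \hat t_{y\pi} + \hat b_s^T (t_x - \hat t_{x\pi}), \qquad
  \hat b_s = \Big(\sum_s d_k q_k x_k x_k^T\Big)^{-1} \sum_s d_k q_k x_k y_k.$$
We take $q_k = 1$ everywhere; the factors are carried through the formulas and
exposed in `survey_sample()` for completeness.

## Endogeneity and the IV correction

GREG is motivated by the working model $y = X\beta + e$. When an auxiliary is
*endogenous* — correlated with $e$ — the implicit slope $\hat b_s$ no longer
estimates $\beta$: its limit acquires the classical omitted-shock bias
$\mathrm{Var}(x)^{-1}\mathrm{Cov}(x, e)$. The instrumental-variable remedy
pairs each endogenous auxiliary with an instrument $z_j$ correlated with $x_j$
but independent of $e$, and replaces $x$ by $z$ on the *left* of every
cross-product while the calibration constraint stays on $x$. Exogenous columns
are their own instruments, so $Z$ keeps the dimension of $X$ and all inverses
are ordinary ($p \times p$): the exactly identified case. Over-identified
systems (more instruments than endogenous variables) are rejected with a
typed error; 2SLS/GMM is out of scope.

Two flavours are implemented:

* **Model-assisted (design-based) IVC.** Weights
  $W = d + \Pi_s^{-1} Z_s \lambda$ with $\lambda$ solving the constraint on
  $X$; the estimator is
  $\hat t_{IVC} = \hat t_{y\pi} + (t_x - \hat t_{x\pi})^T \hat\beta_{IVC}$,
  $\hat\beta_{IVC} = (Z_s^T \Pi_s^{-1} X_s)^{-1} Z_s^T \Pi_s^{-1} y_s$, where
  $\Pi_s^{-1} = \mathrm{diag}(q_k d_k)$. With $Z = X$ this is exactly GREG.
  Its plug-in asymptotic variance replaces $y$ by the IV residuals in the
  SRSWOR variance: $N^2(1 - n/N)\, s^2_e / n$.
* **Model-based MBIVC.** Observed units get weight 1 and the non-sampled part
  of the total is predicted through the IV slope:
  $\hat t_{MBIVC} = \sum_s y_k + t_{x,U-s}^T \hat\beta_{MBIVC}$,
  $\hat\beta_{MBIVC} = (Z_s^T X_s)^{-1} Z_s^T y_s$, with
  $t_{x,U-s} = t_x - \sum_s x_k$. The accompanying sandwich
  $t_{x,U-s}^T A^{-1} M A^{-T} t_{x,U-s}$ ($A = Z_s^T X_s$,
  $M = \sum_s r_k^2 z_k z_k^T$) quantifies the slope-estimation part of its
  error; see "What the formulas do and do not capture" below.

Every estimator is computed along two algebraically equivalent routes — the
weight path $\sum_s W_k y_k$ and the regression path — and the two are
asserted to agree at run time; a disagreement indicates numerical trouble and
raises an error rather than returning a silently wrong number.

## A note on transposes

The weight formula is stated in the row-vector convention
$W' = d' + g'(Z_s^T \Pi_s^{-1} X_s)^{-1} Z_s^T \Pi_s^{-1}$ with
$g = t_x - X_s^T d$. In column convention this is a solve against the
*transpose*, $\lambda = (X_s^T \Pi_s^{-1} Z_s)^{-1} g$: only that orientation
satisfies the calibration constraint on $X$ when $Z \neq X$ (the cross-Gram is
not symmetric). The same applies to the MBIVC weights. The unit tests pin this
down by recomputing $\sum_s W_k x_k - t_x$ independently of the solver.

## The synthetic data-generating process

`generate_population()` draws, for a `dgp_config()`:

* errors $e \sim N(0, \sigma_e^2)$, i.i.d.;
* exogenous auxiliaries $x_j \sim N(0, 1)$ with $z_j = x_j$;
* endogenous auxiliaries through the first stage
  $x_j = \delta z_j + \gamma e + \nu_j$, $z_j \sim N(0,1)$ independent of $e$,
  $\nu_j \sim N(0, \sigma_\nu^2)$;
* $y = X\beta + e$.

So $\gamma$ is the endogeneity loading, $\delta$ the instrument strength, and
the implied correlations are
$\mathrm{corr}(x_j, e) = \gamma\sigma_e/s$ and
$\mathrm{corr}(x_j, z_j) = \delta/s$ with
$s = \sqrt{\delta^2 + \gamma^2\sigma_e^2 + \sigma_\nu^2}$. The defaults
($N = 1000$, $p = 20$, $\beta = 1$,
$\delta = \gamma = \sigma_e = \sigma_\nu = 1$) put both correlations at
$1/\sqrt3 \approx 0.577$: moderate endogeneity with a strong first stage, a
regime where OLS is clearly inconsistent (asymptotic bias
$\gamma\sigma_e^2/\mathrm{Var}(x_j) = 1/3$ on the endogenous coordinate) yet
the IV cross-products stay well conditioned. These loadings are design
choices: a plausible middle ground between negligible endogeneity (where the
correction is pointless) and a weak-instrument regime (which the package
deliberately guards against rather than models). All loadings are
config-exposed.

What the generator does *not* emulate about real survey data: non-normal and
skewed auxiliaries, heteroskedastic or clustered errors, nonzero column
means, item nonresponse, and unequal-probability designs. Passing tests
therefore demonstrate correctness of the estimators and their documented
behaviour under a clean Gaussian superpopulation, not robustness to those
features.

## The Monte-Carlo harness

`run_monte_carlo()` follows the fixed-population design: one population is
generated per configuration and held fixed; each replicate redraws an SRSWOR
sample and recomputes every requested estimator. Reported per cell
(estimator × $n$): $\mathrm{Bias} = \overline{\hat t} - t_y$,
$\mathrm{MSE} = R^{-1}\sum_i (\hat t_i - t_y)^2$, the empirical variance
(denominator $R$, so MSE $=$ variance $+$ bias$^2$ holds exactly), and
`R_effective`. Replicate $r$ at size $n$ uses the deterministic child seed
$(\text{seed} + 10^6 n + r) \bmod (2^{31}-1)$, so any cell is reproducible in
isolation and results do not depend on loop order. Replicates where an
estimator hits a singular or weak-instrument cross-product are dropped for
that estimator and counted; a failure rate above 10% in a cell aborts the run
as a degenerate configuration rather than reporting a misleading average.

Problem sizes used by the shipped tests and the acceptance script: the
comparison grid $n \in \{50, 200\}$ at $R = 500$, variance calibration at
$n = 200$ with $R$ between 1000 and 2000, slope recovery at
$m = 10^5$ population draws. These keep a full run in the low minutes on one
core while leaving Monte-Carlo noise near the percent level.

## What the simulations show — and what the formulas do not capture

Two findings are worth stating plainly, because they are properties of the
estimators, not implementation artifacts; both are recomputed by the test
suite and `scripts/acceptance.R` on every run.

**IVC buys slope consistency, not design efficiency.** From a fixed
population, the GREG slope converges to the census OLS fit — by construction
the residual-variance-minimizing slope — so GREG attains the smallest
asymptotic design variance of any estimator of the form
$\hat t_{y\pi} + c^T(t_x - \hat t_{x\pi})$. The IV slope converges to $\beta$
instead, leaving residuals with variance $\sigma_e^2$ rather than
$\sigma_e^2(1 - \rho^2)$, $\rho = \mathrm{corr}(x, e)$. At the default
loadings that is a factor $1/(1 - 1/3) = 1.5$, and the measured
MSE(IVC)/MSE(GREG) ratio at $n = 200$ is indeed about $1.4$. Both calibrated
estimators beat HT by an order of magnitude, and only the IV-based slopes
recover $\beta$; the right reading is that IVC targets the *structural*
relationship (and inherits GREG's near design-unbiasedness), while GREG is the
better pure total-predictor on a fixed population even when auxiliaries are
endogenous.

**The MBIVC sandwich is a slope-error term, not a full MSE.** The prediction
error of $\hat t_{MBIVC}$ decomposes as
$t_{x,U-s}^T(\hat\beta - \beta) - \sum_{U-s} e_k$. The sandwich estimates the
variance of the first term only; the second contributes roughly
$(N - n)\sigma_e^2$ under the model (plus, over repeated samples from one
fixed population, a design-bias term driven by the realized error total
$t_e$). With $N = 1000$, $n = 200$, $\sigma_e = 1$ the omitted part dominates,
and the measured sandwich-to-empirical-MSE ratio is around $0.1$–$0.3$
depending on the realized population. The sandwich is therefore reported as a
diagnostic of slope uncertainty; it should not be read as a confidence
interval half-width for the total. The model-assisted plug-in variance, by
contrast, tracks the empirical variance of $\hat t_{IVC}$ within about 10% at
$n = 200$.

## Numerical choices

* All $p \times p$ systems are solved with a pivoted factorization
  (`solve()`); no matrix is explicitly inverted. A reciprocal condition
  number below $10^{-12}$ raises a typed error (`ivcalib_singular_design`
  for rank-deficient designs, `ivcalib_weak_instrument` for near-singular
  instrument cross-Grams) naming the offending columns — explosive weights
  are never returned.
* Newton calibration starts at $\lambda = 0$, with tolerance $10^{-10}$ on
  the maximum relative constraint gap
  $\max_j |\sum_s w_k x_{kj} - t_{xj}| / \max(|t_{xj}|, 1)$ and a 50-iteration
  cap. The chi-square distance is quadratic, so one Newton step is exact and
  the iteration is asserted to stop there; raking typically converges in
  under 10. Non-convergence returns the last iterate flagged
  `converged = FALSE`; a singular Jacobian (possible when raking diverges on
  tiny, ill-conditioned samples) raises the singular-design error.
* Chi-square and IVC weights can be negative; they are reported as-is. No
  bounded or truncated calibration distances are implemented.
* Joint inclusion probabilities under SRSWOR are used analytically
  ($\pi_{kl} = n(n-1)/(N(N-1))$), collapsing the $\Delta_{kl}$ double sums to
  the closed forms $N^2(1 - n/N) s^2 / n$; no $n \times n$ matrix is formed.
* The MBIVC sandwich defaults its residual reference slope to
  $\hat\beta_{MBIVC}$ (computable from the sample); an override parameter
  accepts an external slope, which the oracle tests use where the
  superpopulation limit is known. Printed forms of the corresponding bias
  expressions mix incompatible shapes and are not implemented as numeric
  estimators; bias is assessed empirically by the Monte-Carlo harness.

## Limitations

Only SRSWOR is implemented end-to-end (the `survey_sample` contract carries
general $\pi_k$, so unequal-probability extensions are possible but
untested). Exact identification only. The variance formulas are asymptotic
plug-ins; at $n$ close to $p$ they inherit the small-sample optimism of any
residual-based estimator. The generator's Gaussianity caveats above apply to
every simulation-based claim.
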