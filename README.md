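# ivcalib

Estimation of finite-population totals by survey calibration when some
auxiliary variables are **endogenous** — correlated with the errors of the
working linear model — using instrumental variables in the calibration
cross-products.

## Who this is for

Survey statisticians and quantitative epidemiologists who estimate population
totals from probability samples with known auxiliary totals (registers,
censuses, administrative data), and who suspect that one or more auxiliaries
is driven by the same unobserved shocks as the study variable — e.g. a
climate covariate that co-moves with the disturbances of a yield model.

## The estimators

With design weights $d_k = 1/\pi_k$ ($\pi_k = n/N$ under SRSWOR), known
auxiliary totals $t_x$, and instruments $z_k$ (each exogenous auxiliary is its
own instrument, so $Z$ has the same $p$ columns as $X$ — exact
identification):

* **Horvitz–Thompson**: $\hat t_{y\pi} = \sum_s d_k y_k$, with SRSWOR design
  variance $N^2(1 - n/N)\,s^2_y/n$.
* **GREG / chi-square calibration**:
  $\hat t_{GREG} = \hat t_{y\pi} + \hat b_s^T (t_x - \hat t_{x\pi})$ with
  $\hat b_s = (\sum_s d_k q_k x_k x_k^T)^{-1} \sum_s d_k q_k x_k y_k$;
  equivalently $\sum_s w_k y_k$ with $w_k = d_k(1 + q_k x_k^T\lambda)$.
  A Newton iteration covers general distance functions (raking included).
* **Model-assisted IVC**:
  $\hat t_{IVC} = \hat t_{y\pi} + (t_x - \hat t_{x\pi})^T \hat\beta_{IVC}$,
  $\hat\beta_{IVC} = (Z_s^T \Pi_s^{-1} X_s)^{-1} Z_s^T \Pi_s^{-1} y_s$,
  $\Pi_s^{-1} = \mathrm{diag}(q_k d_k)$; reduces exactly to GREG when
  $Z = X$. Plug-in asymptotic variance from IV residuals.
* **Model-based MBIVC**:
  $\hat t_{MBIVC} = \sum_s y_k + t_{x,U-s}^T \hat\beta_{MBIVC}$,
  $\hat\beta_{MBIVC} = (Z_s^T X_s)^{-1} Z_s^T y_s$, plus a sandwich estimate
  of the slope-error contribution to its MSE.

All calibrated weights satisfy $\sum_s W_k x_k = t_x$ to machine precision —
the constraint always binds on $X$, the instruments only steer the
adjustment direction. A synthetic-population generator with controllable
endogeneity ($x_j = \delta z_j + \gamma e + \nu_j$) and a Monte-Carlo harness
(fixed population, repeated SRSWOR, Bias/MSE per estimator × sample size)
round out the package. See `vignettes/iv-calibration.Rmd` for the model,
defaults and numerical choices.

## Worked example

```r
library(ivcalib)

cfg <- dgp_config(N = 1000, p = 20, endogenous_idx = 1, seed = 42)
pop <- generate_population(cfg)
pop
#> Finite population: N = 1000 units, p = 20 auxiliary variables
#>   endogenous columns: 1
#>   t_y = -89.7608

s   <- draw_srswor(pop, 200, seed = 7)
idx <- s$indices
y_s <- pop$y[idx]; X_s <- pop$X[idx, ]; Z_s <- pop$Z[idx, ]

ht_total(s, y_s)
#> HT estimate of t_y: -349.315
greg_total(s, y_s, X_s, pop$t_x)
#> GREG estimate of t_y: -114.846
ivc_total(s, y_s, X_s, Z_s, pop$t_x)
#> IVC estimate of t_y: -94.1376
mbivc_total(y_s, X_s, Z_s, pop$t_x - colSums(X_s))
#> MBIVC estimate of t_y: -77.0378
```

The true total is $-89.8$: both calibrated estimators land far closer than
HT, and the IV slope — unlike the calibration slope — recovers the structural
coefficient on the endogenous column:

```r
greg_total(s, y_s, X_s, pop$t_x)$beta[1]        # 1.372  (OLS-type, biased)
ivc_total(s, y_s, X_s, Z_s, pop$t_x)$beta[1]    # 1.009  (IV, consistent; true beta = 1)
```

A small Monte-Carlo comparison (one fixed population, 500 SRSWOR replicates
per cell):

```r
sm <- run_monte_carlo(simulation_config(cfg, sample_sizes = c(50, 200),
                                        R = 500, estimators = c("HT", "GREG", "IVC"),
                                        seed = 1))
summarize_to_table(sm)
#>   sample_size estimator    bias    mse
#> 1          50      GREG  13.186   7198
#> 2          50        HT -46.500 470818
#> 3          50       IVC   5.150  11412
#> 4         200      GREG   1.618   2477
#> 5         200        HT   8.492 101969
#> 6         200       IVC   1.091   3460
```

Calibration cuts the HT mean-square error by well over an order of magnitude
at both sample sizes. IVC pays a moderate design-variance premium over GREG
for its consistent slope — the vignette discusses this trade-off and what the
variance formulas do and do not capture.

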