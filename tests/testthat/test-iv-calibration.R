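test_that("OLS slope: exact fits, hand case, and a direct-minimization oracle", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  cvec <- c(2, -1, 0.5)
  expect_equal(beta_ols(X, drop(X %*% cvec))$beta, cvec, tolerance = 1e-10)
  expect_equal(beta_ols(cbind(1:3), c(2, 4, 6))$beta, 2.0)

  # independent oracle: minimize ||y - Xb||^2 directly
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3); y <- rnorm(20)
  b_pkg <- beta_ols(X, y)$beta
  b_opt <- optim(rep(0, 3), function(b) sum((y - drop(X %*% b))^2),
                 method = "BFGS", control = list(reltol = 1e-14))$par
  expect_equal(b_pkg, b_opt, tolerance = 1e-6)
  expect_equal(b_pkg, unname(coef(lm.fit(X, y))), tolerance = 1e-10)

  expect_error(beta_ols(cbind(1:5, 1:5), rnorm(5)), class = "ivcalib_singular_design")
})

test_that("IV slope collapses to OLS when Z = X and is exact under zero residuals", {
  set.seed(3)
  X <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20)
  expect_equal(beta_iv(X, X, y)$beta, beta_ols(X, y)$beta, tolerance = 1e-10)

  Z <- X + matrix(rnorm(80, sd = 0.3), 20, 4)
  cvec <- c(1, 2, 3, 4)
  expect_equal(beta_iv(X, Z, drop(X %*% cvec))$beta, cvec, tolerance = 1e-8)
})

test_that("IV is consistent under endogeneity while OLS carries the analytic bias", {
  cfg <- dgp_config(N = 100000L, p = 20L, endogenous_idx = 1L, seed = 2024L)
  pop <- generate_population(cfg)
  b_iv <- beta_iv(pop$X, pop$Z, pop$y)$beta
  b_ols <- beta_ols(pop$X, pop$y)$beta
  expect_lt(abs(b_iv[1] - 1), 0.05)
  # plim bias on the endogenous coordinate: gamma*sigma_e^2 / Var(x_endog) = 1/3
  inconsistency <- cfg$gamma * cfg$sigma_e^2 /
    (cfg$delta^2 + cfg$gamma^2 * cfg$sigma_e^2 + cfg$sigma_nu^2)
  expect_lt(abs(abs(b_ols[1] - 1) - inconsistency) / inconsistency, 0.10)
  # exogenous coordinates stay clean for both
  expect_lt(max(abs(b_iv[-1] - 1)), 0.05)
  expect_lt(max(abs(b_ols[-1] - 1)), 0.05)
})

test_that("weak or irrelevant instruments raise a typed error, not explosive output", {
  set.seed(4)
  n <- 30L
  X <- matrix(rnorm(n * 2), n, 2)
  Z <- X; Z[, 1] <- 0  # irrelevant instrument: Z'X singular
  expect_error(beta_iv(X, Z, rnorm(n)), class = "ivcalib_weak_instrument")
  s <- survey_sample(1:n, N = 90)
  expect_error(ivc_weights(s, X, Z, c(1, 2)), class = "ivcalib_weak_instrument")
  expect_error(mbivc_weights(X, Z, c(1, 2)), class = "ivcalib_weak_instrument")
})

test_that("over-identification is rejected (exact identification only)", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  Z3 <- cbind(X, rnorm(20))
  expect_error(beta_iv(X, Z3, rnorm(20)), class = "ivcalib_not_supported")
  expect_error(ivc_weights(survey_sample(1:20, 40), X, Z3, c(1, 2)),
               class = "ivcalib_not_supported")
})

test_that("IVC weights calibrate on X even when Z differs from X", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    W <- ivc_weights(inst$s, inst$X_s, inst$Z_s, inst$t_x)
    expect_lt(constraint_gap_of(W$w, inst$X_s, inst$t_x), 1e-10)
    if (!isTRUE(all.equal(inst$Z_s, inst$X_s, check.attributes = FALSE))) {
      cw <- chisq_calibration_weights(inst$s, inst$X_s, inst$t_x)
      expect_false(isTRUE(all.equal(W$w, cw$w)))
    }
  }
  # pre-satisfied constraints: W = d exactly
  inst <- random_instance(11)
  t_xpi <- drop(crossprod(inst$X_s, inst$s$d))
  W <- ivc_weights(inst$s, inst$X_s, inst$Z_s, t_xpi)
  expect_equal(W$w, inst$s$d, tolerance = 1e-12)
})

test_that("IVC reduces to chi-square calibration / GREG when Z = X", {
  for (seed in 1:10) {
    inst <- random_instance(seed, zx_equal = TRUE)
    expect_equal(ivc_weights(inst$s, inst$X_s, inst$X_s, inst$t_x)$w,
                 chisq_calibration_weights(inst$s, inst$X_s, inst$t_x)$w,
                 tolerance = 1e-10)
    expect_equal(ivc_total(inst$s, inst$y_s, inst$X_s, inst$X_s, inst$t_x)$estimate,
                 greg_total(inst$s, inst$y_s, inst$X_s, inst$t_x)$estimate,
                 tolerance = 1e-10)
  }
})

test_that("IVC total: zero-residual exactness and dual-path identity on a tiny case", {
  inst <- random_instance(12)
  cvec <- rep(1, inst$p)
  expect_equal(ivc_total(inst$s, drop(inst$X_s %*% cvec), inst$X_s, inst$Z_s,
                         inst$t_x)$estimate,
               sum(inst$t_x * cvec), tolerance = 1e-8)

  pop <- toy_population(N = 8, p = 2, seed = 13, endogenous = TRUE)
  s <- draw_srswor(pop, 4, seed = 1)
  idx <- s$indices
  te <- ivc_total(s, pop$y[idx], pop$X[idx, ], pop$Z[idx, ], pop$t_x)
  w <- ivc_weights(s, pop$X[idx, ], pop$Z[idx, ], pop$t_x)$w
  expect_equal(te$estimate, sum(w * pop$y[idx]), tolerance = 1e-10)
  expect_length(te$beta, 2)
})

test_that("IVC plug-in variance vanishes for perfect fits and censuses", {
  inst <- random_instance(14)
  cvec <- rep(2, inst$p)
  expect_equal(ivc_asymptotic_variance(inst$s, drop(inst$X_s %*% cvec),
                                       inst$X_s, inst$Z_s, inst$t_x), 0,
               tolerance = 1e-12)
  pop <- toy_population(N = 15, p = 2, seed = 15, endogenous = TRUE)
  census <- census_sample(pop)
  expect_equal(ivc_asymptotic_variance(census, pop$y, pop$X, pop$Z, pop$t_x), 0,
               tolerance = 1e-10)
})

test_that("MBIVC weights: census gives unit weights; Z = X gives projection weights", {
  set.seed(16)
  X_s <- matrix(rnorm(24), 12, 2)
  expect_equal(mbivc_weights(X_s, X_s, c(0, 0))$w, rep(1, 12), tolerance = 1e-12)

  t_xns <- c(3, -1)
  W <- mbivc_weights(X_s, X_s, t_xns)$w
  proj <- 1 + drop(X_s %*% solve(crossprod(X_s), t_xns))
  expect_equal(W, proj, tolerance = 1e-10)
})

test_that("MBIVC: constraint on X, dual-path identity, exactness cases", {
  for (seed in 1:6) {
    inst <- random_instance(seed + 30)
    W <- mbivc_weights(inst$X_s, inst$Z_s, inst$t_xns)
    expect_lt(constraint_gap_of(W$w, inst$X_s, inst$t_x), 1e-10)
    te <- mbivc_total(inst$y_s, inst$X_s, inst$Z_s, inst$t_xns)
    expect_equal(te$estimate, sum(W$w * inst$y_s), tolerance = 1e-8)
    cvec <- rep(1, inst$p)
    expect_equal(mbivc_total(drop(inst$X_s %*% cvec), inst$X_s, inst$Z_s,
                             inst$t_xns)$estimate,
                 sum(inst$t_x * cvec), tolerance = 1e-8)
  }
  pop <- toy_population(N = 10, p = 2, seed = 17, endogenous = TRUE)
  expect_equal(mbivc_total(pop$y, pop$X, pop$Z, c(0, 0))$estimate, pop$t_y,
               tolerance = 1e-10)
})

test_that("MBIVC sandwich MSE is nonnegative and zero in the degenerate cases", {
  inst <- random_instance(40)
  cvec <- rep(1, inst$p)
  expect_equal(mbivc_mse(drop(inst$X_s %*% cvec), inst$X_s, inst$Z_s,
                         inst$t_xns, beta_ref = cvec), 0, tolerance = 1e-12)
  expect_equal(mbivc_mse(inst$y_s, inst$X_s, inst$Z_s,
                         rep(0, inst$p)), 0, tolerance = 1e-12)
  expect_gte(mbivc_mse(inst$y_s, inst$X_s, inst$Z_s, inst$t_xns), 0)
})

test_that("slope recovery: IV-based slopes converge to beta, the GREG slope does not", {
  cfg <- dgp_config(N = 10000L, p = 20L, endogenous_idx = 1L, seed = 31L)
  pop <- generate_population(cfg)
  R <- 200L; n <- 2000L
  b_ivc <- b_mb <- b_greg <- numeric(R)
  for (r in seq_len(R)) {
    s <- draw_srswor(pop, n, seed = 50000 + r)
    idx <- s$indices
    y <- pop$y[idx]; X <- pop$X[idx, ]; Z <- pop$Z[idx, ]
    b_ivc[r] <- ivc_total(s, y, X, Z, pop$t_x)$beta[1]
    b_mb[r] <- mbivc_total(y, X, Z, pop$t_x - colSums(X))$beta[1]
    b_greg[r] <- greg_total(s, y, X, pop$t_x)$beta[1]
  }
  expect_lt(median(abs(b_ivc - 1)), 0.05)
  expect_lt(median(abs(b_mb - 1)), 0.05)
  inconsistency <- 1 / 3  # gamma*sigma_e^2 / Var(x_endog) at the default loadings
  expect_lt(abs(median(abs(b_greg - 1)) - inconsistency) / inconsistency, 0.25)
})
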