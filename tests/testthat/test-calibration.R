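test_that("chi-square weights: pre-satisfied constraints give lambda = 0, w = d", {
  pop <- toy_population(N = 20, p = 2, seed = 1)
  census <- census_sample(pop)
  cw <- chisq_calibration_weights(census, pop$X, pop$t_x)
  expect_equal(cw$lam, rep(0, 2), tolerance = 1e-12)
  expect_equal(cw$w, census$d, tolerance = 1e-12)
  expect_lt(cw$constraint_gap, 1e-8)
})

test_that("chi-square weights with x = 1 calibrated to N are the ratio adjustment", {
  # closed form with q = 1: w_k = d_k (1 + lambda) with lambda = (N - sum d)/sum d,
  # i.e. w = d * N / sum(d); under SRSWOR (constant d) this is N/n for every unit
  N <- 60L; n <- 12L
  set.seed(21)
  s <- survey_sample(sample(N, n), N = N, pi = runif(n, 0.1, 0.9))
  cw <- chisq_calibration_weights(s, matrix(1, n, 1), N)
  expect_equal(cw$w, s$d * N / sum(s$d), tolerance = 1e-10)
  expect_equal(sum(cw$w), N)

  srs <- survey_sample(sample(N, n), N = N)
  expect_equal(chisq_calibration_weights(srs, matrix(1, n, 1), N)$w,
               rep(N / n, n), tolerance = 1e-12)
})

test_that("Newton with chi-square distance reproduces the closed form in one step", {
  for (seed in 1:5) {
    inst <- random_instance(seed, zx_equal = TRUE)
    closed <- chisq_calibration_weights(inst$s, inst$X_s, inst$t_x)
    newton <- newton_calibration_weights(inst$s, inst$X_s, inst$t_x, "chisq")
    expect_equal(newton$w, closed$w, tolerance = 1e-10)
    expect_identical(newton$n_iter, 1L)
    expect_true(newton$converged)
  }
})

test_that("raking: satisfied constraints stop immediately; constant x gives ratio weights", {
  pop <- toy_population(N = 30, p = 1, seed = 2)
  census <- census_sample(pop)
  nr <- newton_calibration_weights(census, pop$X, pop$t_x, "raking")
  expect_true(nr$converged)
  expect_lte(nr$n_iter, 1L)
  expect_equal(nr$w, census$d, tolerance = 1e-10)

  # p = 1, x = 1, t_x = N: exp-family calibration is the ratio adjustment
  N <- 50L; n <- 10L
  s <- survey_sample(sample(N, n), N = N, pi = runif(n, 0.1, 0.5))
  nr <- newton_calibration_weights(s, matrix(1, n, 1), N, "raking")
  expect_true(nr$converged)
  expect_equal(nr$w, s$d * (N / sum(s$d)), tolerance = 1e-8)
})

test_that("non-convergence returns the last iterate flagged, without an exception", {
  pop <- toy_population(N = 40, p = 2, seed = 3)
  s <- draw_srswor(pop, 8, seed = 1)
  res <- newton_calibration_weights(s, pop$X[s$indices, ], pop$t_x,
                                    "raking", tol = 1e-10, max_iter = 1L)
  expect_false(res$converged)
  expect_identical(res$n_iter, 1L)
  expect_true(is.finite(res$constraint_gap))
})

test_that("chi-square weights may go negative and are not clipped", {
  # a unit with a large x value and a total far below the HT estimate forces
  # negative weights under the chi-square distance
  n <- 5L; N <- 50L
  X_s <- matrix(c(1, 1, 1, 1, 20), 5, 1)
  s <- survey_sample(1:5, N = N)
  cw <- chisq_calibration_weights(s, X_s, t_x = 10)
  expect_true(any(cw$w < 0))
  expect_lt(cw$constraint_gap, 1e-8)
})

test_that("GREG: exact under a linear model, collapses to HT, dual path agrees", {
  for (seed in 1:5) {
    inst <- random_instance(seed, zx_equal = TRUE)
    cvec <- seq_len(inst$p)
    y_lin <- drop(inst$X_s %*% cvec)
    expect_equal(greg_total(inst$s, y_lin, inst$X_s, inst$t_x)$estimate,
                 sum(inst$t_x * cvec), tolerance = 1e-8)
    # t_x = HT totals of the sample -> GREG = HT
    t_xpi <- drop(crossprod(inst$X_s, inst$s$d))
    expect_equal(greg_total(inst$s, inst$y_s, inst$X_s, t_xpi)$estimate,
                 ht_total(inst$s, inst$y_s)$estimate, tolerance = 1e-10)
    # dual path: weights times y equals the regression form
    g <- greg_total(inst$s, inst$y_s, inst$X_s, inst$t_x)
    w <- chisq_calibration_weights(inst$s, inst$X_s, inst$t_x)$w
    expect_equal(g$estimate, sum(w * inst$y_s), tolerance = 1e-8)
  }
})

test_that("GREG slope equals the weighted least-squares fit (independent oracle)", {
  inst <- random_instance(42, zx_equal = TRUE)
  g <- greg_total(inst$s, inst$y_s, inst$X_s, inst$t_x)
  fit <- lm.wfit(inst$X_s, inst$y_s, w = inst$s$d * inst$s$q)
  expect_equal(unname(g$beta), unname(coef(fit)), tolerance = 1e-8)
})

test_that("rank-deficient designs raise a typed error naming columns", {
  n <- 10L
  set.seed(8)
  X_s <- cbind(a = rnorm(n), b = rnorm(n))
  X_s <- cbind(X_s, c = X_s[, "a"] + X_s[, "b"])  # exact collinearity
  s <- survey_sample(1:n, N = 40)
  err <- tryCatch(chisq_calibration_weights(s, X_s, c(1, 2, 3)),
                  error = function(e) e)
  expect_s3_class(err, "ivcalib_singular_design")
  expect_match(conditionMessage(err), "rank-deficient")
  expect_error(greg_total(s, rnorm(n), X_s, c(1, 2, 3)),
               class = "ivcalib_singular_design")
})

test_that("weights writer round-trips unit ids, d, w and diagnostics", {
  inst <- random_instance(5, zx_equal = TRUE)
  cw <- chisq_calibration_weights(inst$s, inst$X_s, inst$t_x)
  csv <- tempfile(fileext = ".csv")
  write_weights_csv(cw, inst$s, csv)
  back <- read.csv(csv)
  expect_equal(back$unit_id, inst$s$indices)
  expect_equal(back$w, cw$w, tolerance = 1e-12)
  diag <- jsonlite::read_json(paste0(csv, ".diag.json"), simplifyVector = TRUE)
  expect_equal(diag$lambda, cw$lam, tolerance = 1e-12)
  expect_true(diag$converged)
})
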