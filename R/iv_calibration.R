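#' Slope estimators: OLS and instrumental-variable
#'
#' `beta_ols()` solves the normal equations \eqn{(X^T X)^{-1} X^T y};
#' `beta_iv()` the exactly identified IV estimator \eqn{(Z^T X)^{-1} Z^T y},
#' consistent when the instruments are correlated with their endogenous
#' regressors but uncorrelated with the error. `Z` must have exactly as many
#' columns as `X` (exact identification); over-identified systems are not
#' supported.
#'
#' @param X m x p regressor matrix.
#' @param Z m x p instrument matrix (exogenous columns are their own
#'   instruments).
#' @param y response vector of length m.
#' @return An object of class `slope_estimate`: list with `beta`, `method`
#'   (`"OLS"` or `"IV"`) and `gram_condition`, the reciprocal condition number
#'   of the solved cross-product matrix.
#' @examples
#' X <- cbind(1:3); beta_ols(X, c(2, 4, 6))$beta  # 2
#' @export
beta_ols <- function(X, y) {
  X <- as_numeric_matrix(X, "X"); y <- as.numeric(y)
  if (nrow(X) < ncol(X))
    stop_ivcalib("ivcalib_singular_design", "fewer observations than regressors")
  b <- guarded_solve(crossprod(X), crossprod(X, y), "ivcalib_singular_design", "X'X")
  slope_estimate(drop(b), "OLS", attr(b, "rcond"))
}

#' @rdname beta_ols
#' @export
beta_iv <- function(X, Z, y) {
  X <- as_numeric_matrix(X, "X"); Z <- as_numeric_matrix(Z, "Z"); y <- as.numeric(y)
  check_exact_identification(X, Z)
  b <- guarded_solve(crossprod(Z, X), crossprod(Z, y), "ivcalib_weak_instrument", "Z'X")
  slope_estimate(drop(b), "IV", attr(b, "rcond"))
}

slope_estimate <- function(beta, method, gram_condition) {
  beta <- as.numeric(beta)  # strip solver attributes
  if (any(!is.finite(beta)))
    stop_ivcalib("ivcalib_internal_error", "non-finite slope estimate")
  structure(list(beta = beta, method = method, gram_condition = gram_condition),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("%s slope estimate (p = %d, gram rcond %.3g):\n",
              x$method, length(x$beta), x$gram_condition))
  print(x$beta)
  invisible(x)
}

check_exact_identification <- function(X, Z) {
  if (!identical(dim(X), dim(Z)))
    stop_ivcalib("ivcalib_not_supported",
                 sprintf("exact identification requires Z (%d x %d) to match X (%d x %d) column-for-column; over-identified systems are not supported",
                         nrow(Z), ncol(Z), nrow(X), ncol(X)))
}

#' Model-assisted instrumental-variable calibration (IVC) weights
#'
#' Calibration weights of the form \eqn{W = d + \Pi_s^{-1} Z_s \lambda}, with
#' \eqn{\lambda} chosen so that the calibration constraint holds **on X**
#' (\eqn{\sum_s W_k x_k = t_x}) while the adjustment direction is spanned by
#' the instruments: \eqn{\lambda = (X_s^T \Pi_s^{-1} Z_s)^{-1}(t_x - X_s^T d)}.
#' With `Z_s = X_s` this reduces exactly to [chisq_calibration_weights()].
#'
#' @inheritParams chisq_calibration_weights
#' @param Z_s n x p instrument matrix for the sampled units.
#' @return A `calibration_weights` object (method `"ivc"`).
#' @export
ivc_weights <- function(sample, X_s, Z_s, t_x) {
  stopifnot(inherits(sample, "survey_sample"))
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  check_exact_identification(X_s, Z_s)
  if (nrow(X_s) != sample$n) stop_ivcalib("ivcalib_alignment_error", "X_s must have one row per sampled unit")
  t_x <- as.numeric(t_x)
  qd <- sample_design_diag(sample)
  A <- crossprod(Z_s, qd * X_s)            # Z' Pi^{-1} X
  g <- t_x - drop(crossprod(X_s, sample$d))
  lam <- drop(guarded_solve(t(A), g, "ivcalib_weak_instrument", "X' Pi^{-1} Z"))
  w <- sample$d + qd * drop(Z_s %*% lam)
  calibration_weights(w, lam, "ivc", TRUE, 1L, constraint_gap(w, X_s, t_x), d = sample$d)
}

#' Model-assisted IVC estimator of a population total
#'
#' \eqn{\hat t_{IVC} = \hat t_{y\pi} + (t_x - \hat t_{x\pi})^T \hat\beta_{IVC}}
#' with \eqn{\hat\beta_{IVC} = (Z_s^T \Pi_s^{-1} X_s)^{-1} Z_s^T \Pi_s^{-1} y_s}.
#' Identical to \eqn{\sum_s W_k y_k} with [ivc_weights()]; both paths are
#' computed and checked to agree to 1e-8 relative.
#'
#' @inheritParams ivc_weights
#' @param y_s study-variable values for the sampled units.
#' @return A `total_estimate` (tag `"IVC"`) carrying \eqn{\hat\beta_{IVC}}.
#' @export
ivc_total <- function(sample, y_s, X_s, Z_s, t_x) {
  stopifnot(inherits(sample, "survey_sample"))
  y_s <- check_alignment(sample, y_s)
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  check_exact_identification(X_s, Z_s)
  t_x <- as.numeric(t_x)
  qd <- sample_design_diag(sample)
  A <- crossprod(Z_s, qd * X_s)
  b <- drop(guarded_solve(A, drop(crossprod(Z_s, qd * y_s)),
                          "ivcalib_weak_instrument", "Z' Pi^{-1} X"))
  t_ypi <- sum(sample$d * y_s)
  t_xpi <- drop(crossprod(X_s, sample$d))
  est <- t_ypi + sum(b * (t_x - t_xpi))
  w_est <- sum(ivc_weights(sample, X_s, Z_s, t_x)$w * y_s)
  if (abs(w_est - est) > 1e-8 * max(1, abs(est)))
    stop_ivcalib("ivcalib_internal_error",
                 sprintf("IVC weight path (%.10g) and regression path (%.10g) disagree", w_est, est))
  total_estimate(est, "IVC", beta = b)
}

#' Plug-in asymptotic variance of the IVC estimator
#'
#' Sample plug-in of the design variance of [ivc_total()]: residuals
#' \eqn{e_k = y_k - x_k^T \hat\beta_{IVC}} replace \eqn{y_k} in the SRSWOR
#' Horvitz-Thompson variance, giving \eqn{N^2 (1 - n/N) s^2_e / n}.
#'
#' @inheritParams ivc_total
#' @return Nonnegative scalar variance estimate.
#' @seealso [ivc_design_variance_population()] for the population-level form.
#' @export
ivc_asymptotic_variance <- function(sample, y_s, X_s, Z_s, t_x) {
  stopifnot(inherits(sample, "survey_sample"))
  y_s <- check_alignment(sample, y_s)
  if (sample$n < 2L)
    stop_ivcalib("ivcalib_undefined_variance", "variance estimation requires n >= 2")
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  qd <- sample_design_diag(sample)
  A <- crossprod(Z_s, qd * X_s)
  b <- drop(guarded_solve(A, drop(crossprod(Z_s, qd * y_s)),
                          "ivcalib_weak_instrument", "Z' Pi^{-1} X"))
  e <- y_s - drop(X_s %*% b)
  ht_variance(sample, e)
}

#' Population-level design variance of the IVC estimator
#'
#' Evaluates \eqn{N^2 (1 - n/N) S^2_E / n} with population residuals
#' \eqn{E_k = y_k - x_k^T \beta} (variance denominator N - 1) — the SRSWOR
#' closed form of the \eqn{\Delta_{kl}} double sum over the whole universe.
#' Intended for validation against Monte-Carlo variance, not for estimation
#' from a sample.
#'
#' @param population a [finite_population()].
#' @param beta slope vector defining the residuals.
#' @param n the sample size the variance refers to.
#' @return Nonnegative scalar.
#' @export
ivc_design_variance_population <- function(population, beta, n) {
  stopifnot(inherits(population, "finite_population"))
  E <- population$y - drop(population$X %*% as.numeric(beta))
  N <- population$N
  N^2 * (1 - n / N) * stats::var(E) / n
}

#' Model-based IVC (MBIVC) weights
#'
#' Prediction weights \eqn{W = 1_s + Z_s (Z_s^T X_s)^{-T} t_{x,U-s}} where
#' \eqn{t_{x,U-s} = t_x - \sum_s x_k} are the auxiliary totals over the
#' non-sampled units. The weights satisfy \eqn{\sum_s W_k x_k = t_x}; design
#' weights play no role (model-based inference).
#'
#' @param X_s,Z_s n x p auxiliary and instrument matrices for the sample.
#' @param t_x_nonsample auxiliary totals over the non-sampled units (length p).
#' @return A `calibration_weights` object (method `"mbivc"`).
#' @export
mbivc_weights <- function(X_s, Z_s, t_x_nonsample) {
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  check_exact_identification(X_s, Z_s)
  t_xns <- as.numeric(t_x_nonsample)
  A <- crossprod(Z_s, X_s)
  lam <- drop(guarded_solve(t(A), t_xns, "ivcalib_weak_instrument", "X'Z"))
  w <- 1 + drop(Z_s %*% lam)
  t_x <- t_xns + colSums(X_s)
  calibration_weights(w, lam, "mbivc", TRUE, 1L, constraint_gap(w, X_s, t_x),
                      d = rep(1, nrow(X_s)))
}

#' Model-based IVC estimator of a population total
#'
#' \eqn{\hat t_{MBIVC} = \sum_s y_k + t_{x,U-s}^T \hat\beta_{MBIVC}} with
#' \eqn{\hat\beta_{MBIVC} = (Z_s^T X_s)^{-1} Z_s^T y_s}: observed units enter
#' with weight 1 and the non-sampled part of the total is predicted from the
#' working model through the IV slope. Equal to the weight path
#' \eqn{\sum_s W_k y_k} with [mbivc_weights()] (checked to 1e-8 relative).
#'
#' @inheritParams mbivc_weights
#' @param y_s study-variable values for the sampled units.
#' @return A `total_estimate` (tag `"MBIVC"`) carrying \eqn{\hat\beta_{MBIVC}}.
#' @export
mbivc_total <- function(y_s, X_s, Z_s, t_x_nonsample) {
  y_s <- as.numeric(y_s)
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  check_exact_identification(X_s, Z_s)
  if (length(y_s) != nrow(X_s))
    stop_ivcalib("ivcalib_alignment_error", "y_s must have one value per row of X_s")
  t_xns <- as.numeric(t_x_nonsample)
  A <- crossprod(Z_s, X_s)
  b <- drop(guarded_solve(A, crossprod(Z_s, y_s), "ivcalib_weak_instrument", "Z'X"))
  est <- sum(y_s) + sum(t_xns * b)
  w_est <- sum(mbivc_weights(X_s, Z_s, t_xns)$w * y_s)
  if (abs(w_est - est) > 1e-8 * max(1, abs(est)))
    stop_ivcalib("ivcalib_internal_error",
                 sprintf("MBIVC weight path (%.10g) and regression path (%.10g) disagree", w_est, est))
  total_estimate(est, "MBIVC", beta = b)
}

#' Sandwich MSE estimate for the MBIVC estimator
#'
#' Returns the sandwich form
#' \eqn{t_{x,U-s}^T A^{-1} M A^{-T} t_{x,U-s}} with \eqn{A = Z_s^T X_s} and
#' \eqn{M = \sum_s r_k^2 z_k z_k^T}, where \eqn{r_k = y_k - x_k^T \beta_{ref}}.
#' This quantifies the slope-estimation component of the prediction error; it
#' does not include the residual variance of the non-sampled units (see the
#' methods vignette). Always nonnegative.
#'
#' @inheritParams mbivc_total
#' @param beta_ref residual reference slope; defaults to
#'   \eqn{\hat\beta_{MBIVC}} computed from the sample.
#' @return Nonnegative scalar.
#' @export
mbivc_mse <- function(y_s, X_s, Z_s, t_x_nonsample, beta_ref = NULL) {
  y_s <- as.numeric(y_s)
  X_s <- as_numeric_matrix(X_s, "X_s"); Z_s <- as_numeric_matrix(Z_s, "Z_s")
  check_exact_identification(X_s, Z_s)
  t_xns <- as.numeric(t_x_nonsample)
  A <- crossprod(Z_s, X_s)
  if (is.null(beta_ref)) {
    beta_ref <- drop(guarded_solve(A, crossprod(Z_s, y_s), "ivcalib_weak_instrument", "Z'X"))
  } else {
    beta_ref <- as.numeric(beta_ref)
  }
  r <- y_s - drop(X_s %*% beta_ref)
  u <- drop(guarded_solve(t(A), t_xns, "ivcalib_weak_instrument", "X'Z"))
  sum(r^2 * drop(Z_s %*% u)^2)
}
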