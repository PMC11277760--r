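#' @noRd
#' Shared constructor for weight objects. `converged` weight sets must satisfy
#' the calibration equations to 1e-8 relative; violations indicate a numerical
#' problem upstream and raise an error rather than returning silently bad
#' weights.
calibration_weights <- function(w, lam, method, converged, n_iter, gap, d = NULL) {
  if (converged && gap > 1e-8)
    stop_ivcalib("ivcalib_internal_error",
                 sprintf("calibration reported converged but constraint gap is %.3g", gap))
  structure(list(w = as.numeric(w), lam = as.numeric(lam), method = method,
                 converged = converged, n_iter = as.integer(n_iter),
                 constraint_gap = gap, d = d),
            class = "calibration_weights")
}

#' @export
print.calibration_weights <- function(x, ...) {
  cat(sprintf("Calibration weights (%s): n = %d, sum(w) = %.6g\n",
              x$method, length(x$w), sum(x$w)))
  cat(sprintf("  converged: %s after %d iteration(s); max relative constraint gap %.3g\n",
              x$converged, x$n_iter, x$constraint_gap))
  if (any(x$w < 0)) cat(sprintf("  note: %d negative weight(s) (not clipped)\n", sum(x$w < 0)))
  invisible(x)
}

sample_design_diag <- function(sample) sample$q * sample$d  # diag of Pi_s^{-1}

#' Chi-square calibration weights (closed form)
#'
#' Minimizes the chi-square distance \eqn{\sum_s (w_k - d_k)^2 / (d_k q_k)}
#' subject to the calibration equations \eqn{\sum_s w_k x_k = t_x}. The
#' solution is linear in the design weights,
#' \eqn{w_k = d_k (1 + q_k x_k^T \lambda)} with
#' \eqn{\lambda = (\sum_s d_k q_k x_k x_k^T)^{-1} (t_x - \hat t_{x\pi})}.
#' Weights may be negative; they are never clipped.
#'
#' @param sample a [survey_sample()].
#' @param X_s n x p matrix of auxiliary values for the sampled units.
#' @param t_x known population totals of the auxiliary variables (length p).
#' @return A `calibration_weights` object (method `"chisq_closed_form"`).
#' @examples
#' pop <- finite_population(y = rnorm(50), X = cbind(1, rnorm(50)))
#' s <- draw_srswor(pop, 10, seed = 1)
#' cw <- chisq_calibration_weights(s, pop$X[s$indices, ], pop$t_x)
#' sum(cw$w)  # = N because a constant column is calibrated to N
#' @export
chisq_calibration_weights <- function(sample, X_s, t_x) {
  stopifnot(inherits(sample, "survey_sample"))
  X_s <- as_numeric_matrix(X_s, "X_s")
  if (nrow(X_s) != sample$n) stop_ivcalib("ivcalib_alignment_error", "X_s must have one row per sampled unit")
  t_x <- as.numeric(t_x)
  qd <- sample_design_diag(sample)
  A <- crossprod(X_s, qd * X_s)            # X' Pi^{-1} X
  g <- t_x - drop(crossprod(X_s, sample$d))
  lam <- drop(guarded_solve(A, g, "ivcalib_singular_design", "X' Pi^{-1} X"))
  w <- sample$d + qd * drop(X_s %*% lam)
  calibration_weights(w, lam, "chisq_closed_form", TRUE, 1L,
                      constraint_gap(w, X_s, t_x), d = sample$d)
}

#' Calibration weights by Newton iteration
#'
#' Solves the calibration equations for a general weight-generating function
#' \eqn{w_k = d_k F(q_k x_k^T \lambda)}: `distance = "chisq"` uses
#' \eqn{F(u) = 1 + u} (linear, so the iteration finishes in one step and
#' reproduces [chisq_calibration_weights()]); `distance = "raking"` uses
#' \eqn{F(u) = e^u}, the multiplicative raking family with strictly positive
#' weights. Iterates
#' \eqn{\lambda^{v+1} = \lambda^v + J^{-1}\{t_x - \hat t_{x\pi} - \phi_s(\lambda^v)\}}
#' with \eqn{\phi_s(\lambda) = \sum_s d_k (F(u_k) - 1) x_k} and Jacobian
#' \eqn{J = \sum_s d_k F'(u_k) q_k x_k x_k^T}, from \eqn{\lambda = 0}.
#'
#' @inheritParams chisq_calibration_weights
#' @param distance `"chisq"` or `"raking"`.
#' @param tol convergence tolerance on the maximum relative constraint gap.
#' @param max_iter iteration cap; on hitting it the last iterate is returned
#'   with `converged = FALSE` (no error).
#' @return A `calibration_weights` object (method `"newton_chisq"` or
#'   `"newton_raking"`).
#' @export
newton_calibration_weights <- function(sample, X_s, t_x,
                                       distance = c("chisq", "raking"),
                                       tol = 1e-10, max_iter = 50L) {
  stopifnot(inherits(sample, "survey_sample"), tol > 0)
  distance <- match.arg(distance)
  X_s <- as_numeric_matrix(X_s, "X_s")
  if (nrow(X_s) != sample$n) stop_ivcalib("ivcalib_alignment_error", "X_s must have one row per sampled unit")
  t_x <- as.numeric(t_x)
  Ffun <- switch(distance, chisq = function(u) 1 + u, raking = exp)
  Fprime <- switch(distance, chisq = function(u) rep(1, length(u)), raking = exp)
  d <- sample$d; q <- sample$q
  t_xpi <- drop(crossprod(X_s, d))
  lam <- rep(0, ncol(X_s))
  weights_at <- function(lam) d * Ffun(q * drop(X_s %*% lam))
  w <- weights_at(lam)
  gap <- constraint_gap(w, X_s, t_x)
  iter <- 0L
  while (gap > tol && iter < max_iter) {
    u <- q * drop(X_s %*% lam)
    phi <- drop(crossprod(X_s, d * (Ffun(u) - 1)))
    J <- crossprod(X_s, (d * Fprime(u) * q) * X_s)
    step <- drop(guarded_solve(J, t_x - t_xpi - phi, "ivcalib_singular_design",
                               "Newton Jacobian"))
    lam <- lam + step
    w <- weights_at(lam)
    gap <- constraint_gap(w, X_s, t_x)
    iter <- iter + 1L
  }
  calibration_weights(w, lam, paste0("newton_", distance),
                      converged = gap <= tol, n_iter = iter, gap = gap, d = d)
}

#' Generalized regression (GREG) estimator of a total
#'
#' The chi-square calibration estimator in regression form:
#' \eqn{\hat t_{GREG} = \hat t_{y\pi} + \hat b_s^T (t_x - \hat t_{x\pi})} with
#' \eqn{\hat b_s = (\sum_s d_k q_k x_k x_k^T)^{-1} \sum_s d_k q_k x_k y_k}.
#' The weight path \eqn{\sum_s w_k y_k} with [chisq_calibration_weights()] is
#' computed as well and the two are checked to agree to 1e-8 relative — they
#' are the same estimator algebraically.
#'
#' @inheritParams chisq_calibration_weights
#' @param y_s study-variable values for the sampled units.
#' @return A `total_estimate` (tag `"GREG"`) carrying the slope in `$beta`.
#' @export
greg_total <- function(sample, y_s, X_s, t_x) {
  stopifnot(inherits(sample, "survey_sample"))
  y_s <- check_alignment(sample, y_s)
  X_s <- as_numeric_matrix(X_s, "X_s")
  t_x <- as.numeric(t_x)
  qd <- sample_design_diag(sample)
  A <- crossprod(X_s, qd * X_s)
  b <- drop(guarded_solve(A, drop(crossprod(X_s, qd * y_s)),
                          "ivcalib_singular_design", "X' Pi^{-1} X"))
  t_ypi <- sum(sample$d * y_s)
  t_xpi <- drop(crossprod(X_s, sample$d))
  est <- t_ypi + sum(b * (t_x - t_xpi))
  w_est <- sum(chisq_calibration_weights(sample, X_s, t_x)$w * y_s)
  if (abs(w_est - est) > 1e-8 * max(1, abs(est)))
    stop_ivcalib("ivcalib_internal_error",
                 sprintf("GREG weight path (%.10g) and regression path (%.10g) disagree", w_est, est))
  total_estimate(est, "GREG", beta = b)
}

#' Write calibration weights to CSV with a diagnostics sidecar
#'
#' Emits `unit_id, d, w, method` rows and a JSON file with the Lagrange
#' multiplier, iteration count and constraint gap.
#'
#' @param weights a `calibration_weights` object.
#' @param sample the [survey_sample()] the weights belong to.
#' @param path output CSV path.
#' @param diagnostics_path JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(weights, sample, path,
                              diagnostics_path = paste0(path, ".diag.json")) {
  stopifnot(inherits(weights, "calibration_weights"), inherits(sample, "survey_sample"))
  utils::write.csv(data.frame(unit_id = sample$indices, d = sample$d,
                              w = weights$w, method = weights$method),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(lambda = weights$lam, n_iter = weights$n_iter,
                            constraint_gap = weights$constraint_gap,
                            converged = weights$converged, method = weights$method),
                       diagnostics_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
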