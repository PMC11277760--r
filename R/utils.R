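# Internal helpers: typed conditions, guarded linear solves, seeding.

RCOND_TOL <- 1e-12

stop_ivcalib <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ivcalib_error", "error")))
}

#' @noRd
#' Solve A %*% x = b after checking the reciprocal condition number of A.
#' `error_class` distinguishes rank deficiency of a design matrix
#' ("ivcalib_singular_design") from a near-singular instrument cross-product
#' ("ivcalib_weak_instrument").
guarded_solve <- function(A, b, error_class = "ivcalib_singular_design",
                          what = "cross-product matrix") {
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(rc) || rc < RCOND_TOL) {
    dec <- qr(A)
    bad <- if (dec$rank < ncol(A)) dec$pivot[seq(dec$rank + 1L, ncol(A))] else integer(0)
    nm <- colnames(A)
    bad_lab <- if (length(bad)) {
      paste(if (!is.null(nm)) nm[bad] else paste0("column ", bad), collapse = ", ")
    } else "none isolated"
    stop_ivcalib(error_class,
                 sprintf("%s is singular or numerically rank-deficient (rcond = %.3g < %.0e); offending columns: %s",
                         what, rc, RCOND_TOL, bad_lab),
                 rcond = rc, offending = bad)
  }
  structure(solve(A, b), rcond = rc)
}

# Relative violation of the calibration equations for weights w:
# max_j |sum_s w_k x_kj - t_xj| / max(|t_xj|, 1).
constraint_gap <- function(w, X_s, t_x) {
  got <- drop(crossprod(X_s, w))
  max(abs(got - t_x) / pmax(abs(t_x), 1))
}

# Deterministic child seed for replicate r at sample size n under a master
# seed; kept inside the 32-bit integer range R's RNG accepts.
child_seed <- function(seed, n, r) {
  as.integer((as.numeric(seed) + as.numeric(n) * 1e6 + as.numeric(r)) %% 2147483647)
}

with_seed_if <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

as_numeric_matrix <- function(X, what = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_ivcalib("ivcalib_parse_error", sprintf("%s must be numeric", what))
  storage.mode(X) <- "double"
  X
}
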