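#' Configuration of the synthetic data-generating process
#'
#' Describes a finite population built from the superpopulation model
#' \eqn{y = X\beta + e} in which a chosen subset of auxiliary columns is
#' endogenous. Exogenous columns are standard normal and act as their own
#' instruments (\eqn{z_j = x_j}). Each endogenous column is generated through
#' the first stage \eqn{x_j = \delta z_j + \gamma e + \nu_j} with
#' \eqn{z_j \sim N(0,1)} independent of \eqn{e} and
#' \eqn{\nu_j \sim N(0, \sigma_\nu^2)}: \eqn{\gamma} is the endogeneity
#' loading and \eqn{\delta} the instrument strength. Implied second moments
#' (used by the diagnostics and tests):
#' \deqn{corr(x_j, e) = \gamma\sigma_e / s, \quad
#'       corr(x_j, z_j) = \delta / s, \quad
#'       s = \sqrt{\delta^2 + \gamma^2\sigma_e^2 + \sigma_\nu^2}.}
#' At the defaults (all loadings 1) both correlations are \eqn{1/\sqrt 3}.
#'
#' @param N population size (default 1000).
#' @param p number of auxiliary variables (default 20).
#' @param endogenous_idx indices of the endogenous columns (default 1).
#' @param beta superpopulation slope vector, recycled to length p (default 1).
#' @param sigma_e error standard deviation (> 0, default 1).
#' @param gamma endogeneity loading (>= 0, default 1).
#' @param delta first-stage instrument loading (default 1).
#' @param sigma_nu first-stage noise standard deviation (>= 0, default 1).
#' @param seed optional integer seed recorded in the config.
#' @return An object of class `dgp_config`.
#' @export
dgp_config <- function(N = 1000L, p = 20L, endogenous_idx = 1L,
                       beta = 1, sigma_e = 1, gamma = 1, delta = 1,
                       sigma_nu = 1, seed = NULL) {
  N <- as.integer(N); p <- as.integer(p)
  if (is.na(N) || N < 1L) stop_ivcalib("ivcalib_config_error", "N must be a positive integer")
  if (is.na(p) || p < 1L) stop_ivcalib("ivcalib_config_error", "p must be a positive integer")
  endogenous_idx <- sort(unique(as.integer(endogenous_idx)))
  if (length(endogenous_idx) && (min(endogenous_idx) < 1L || max(endogenous_idx) > p))
    stop_ivcalib("ivcalib_config_error", "endogenous_idx must index columns 1..p")
  if (sigma_e <= 0) stop_ivcalib("ivcalib_config_error", "sigma_e must be > 0")
  if (gamma < 0 || sigma_nu < 0 || delta < 0)
    stop_ivcalib("ivcalib_config_error", "gamma, delta and sigma_nu must be >= 0")
  if (length(endogenous_idx) && gamma > 0 && delta == 0 && sigma_nu == 0)
    stop_ivcalib("ivcalib_config_error",
                 "degenerate first stage: corr(x_j, e) would be 1 (delta = sigma_nu = 0)")
  structure(list(N = N, p = p, endogenous_idx = endogenous_idx,
                 beta = rep_len(as.numeric(beta), p),
                 sigma_e = sigma_e, gamma = gamma, delta = delta,
                 sigma_nu = sigma_nu, seed = seed),
            class = "dgp_config")
}

#' Theoretical correlations implied by a DGP configuration
#'
#' @param config a [dgp_config()].
#' @return List with `corr_x_e` and `corr_x_z` for the endogenous columns.
#' @export
dgp_theoretical_corr <- function(config) {
  stopifnot(inherits(config, "dgp_config"))
  s <- sqrt(config$delta^2 + config$gamma^2 * config$sigma_e^2 + config$sigma_nu^2)
  list(corr_x_e = config$gamma * config$sigma_e / s,
       corr_x_z = config$delta / s)
}

#' Generate a finite population with endogenous auxiliaries
#'
#' Draws the population described by a [dgp_config()]: errors
#' \eqn{e \sim N(0, \sigma_e^2)}, exogenous auxiliaries standard normal with
#' \eqn{z_j = x_j}, endogenous auxiliaries through their first stage, and
#' \eqn{y = X\beta + e}. The realized error vector is attached as attribute
#' `"e"` so diagnostics and oracle tests can reconstruct it without refitting.
#'
#' @param config a [dgp_config()].
#' @param seed optional integer seed; defaults to `config$seed`. Identical
#'   config + seed reproduce the population bit for bit.
#' @return A [finite_population()] with `endogenous_idx` recorded.
#' @examples
#' pop <- generate_population(dgp_config(N = 200, p = 3, seed = 1))
#' pop
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "dgp_config"))
  with_seed_if(seed, {
    N <- config$N; p <- config$p
    e <- stats::rnorm(N, 0, config$sigma_e)
    X <- matrix(stats::rnorm(N * p), N, p)
    Z <- X
    for (j in config$endogenous_idx) {
      Z[, j] <- stats::rnorm(N)
      X[, j] <- config$delta * Z[, j] + config$gamma * e +
        stats::rnorm(N, 0, config$sigma_nu)
    }
    colnames(X) <- paste0("x", seq_len(p))
    colnames(Z) <- paste0("z", seq_len(p))
    y <- drop(X %*% config$beta) + e
    pop <- finite_population(y, X, Z, endogenous_idx = config$endogenous_idx)
    attr(pop, "e") <- e
    attr(pop, "beta") <- config$beta
    pop
  })
}

#' Diagnostics for a generated (or loaded) population
#'
#' Reports the empirical endogeneity correlations \eqn{corr(x_j, e)} (with
#' \eqn{e} reconstructed as \eqn{y - X\beta} when `beta` is supplied or the
#' population carries its generating slope), the instrument-relevance
#' correlations \eqn{corr(x_j, z_j)}, the instrument-validity correlations
#' \eqn{corr(z_j, e)}, and reciprocal condition numbers of \eqn{X^T X} and
#' \eqn{Z^T X}.
#'
#' @param pop a [finite_population()].
#' @param beta optional slope used to reconstruct the error vector.
#' @return List with elements `corr_x_e`, `corr_z_e` (NULL when no slope is
#'   available), `corr_x_z`, `rcond_xtx`, `rcond_ztx`.
#' @export
diagnose_population <- function(pop, beta = attr(pop, "beta")) {
  stopifnot(inherits(pop, "finite_population"))
  e <- if (!is.null(beta)) pop$y - drop(pop$X %*% rep_len(as.numeric(beta), pop$p))
  corr_xz <- vapply(seq_len(pop$p), function(j) {
    if (stats::sd(pop$Z[, j]) == 0 || stats::sd(pop$X[, j]) == 0) return(NA_real_)
    stats::cor(pop$X[, j], pop$Z[, j])
  }, numeric(1))
  list(corr_x_e = if (!is.null(e)) drop(stats::cor(pop$X, e)),
       corr_z_e = if (!is.null(e)) drop(stats::cor(pop$Z, e)),
       corr_x_z = corr_xz,
       rcond_xtx = rcond(crossprod(pop$X)),
       rcond_ztx = rcond(crossprod(pop$Z, pop$X)))
}
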