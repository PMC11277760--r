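#' Draw a simple random sample without replacement
#'
#' Draws `n` distinct units uniformly from a finite population. Under SRSWOR
#' every first-order inclusion probability is \eqn{\pi_k = n/N}, so the design
#' weight of every sampled unit is \eqn{d_k = N/n}; the calibration tuning
#' factors default to \eqn{q_k = 1}.
#'
#' @param population a [finite_population()].
#' @param n sample size, `1 <= n <= N`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so the
#'   draw is reproducible.
#' @return An object of class `survey_sample`: list with `indices` (sorted,
#'   1-based), `n`, `N`, `pi`, `d`, `q`.
#' @examples
#' pop <- finite_population(y = rnorm(100), X = matrix(rnorm(100), 100, 1))
#' s <- draw_srswor(pop, 10, seed = 1)
#' s$d[1]  # N/n = 10
#' @export
draw_srswor <- function(population, n, seed = NULL) {
  stopifnot(inherits(population, "finite_population"))
  N <- population$N
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L || n > N)
    stop_ivcalib("ivcalib_invalid_sample_size",
                 sprintf("sample size n = %s must satisfy 1 <= n <= N = %d", n, N))
  idx <- with_seed_if(seed, sort(sample.int(N, n, replace = FALSE)))
  survey_sample(idx, N)
}

#' Construct a survey sample
#'
#' Low-level constructor used by [draw_srswor()] and by the estimate-from-data
#' path when the sample is supplied externally. The default `pi` is the SRSWOR
#' value `n/N`.
#'
#' @param indices distinct 1-based unit indices.
#' @param N population size.
#' @param pi first-order inclusion probabilities (recycled scalar allowed).
#' @param q calibration tuning factors, all positive (default 1).
#' @return A `survey_sample` object.
#' @export
survey_sample <- function(indices, N, pi = length(indices) / N, q = 1) {
  indices <- as.integer(indices)
  n <- length(indices)
  if (anyDuplicated(indices) || any(indices < 1L) || any(indices > N))
    stop_ivcalib("ivcalib_config_error", "indices must be distinct and within 1..N")
  pi <- rep_len(as.numeric(pi), n)
  q <- rep_len(as.numeric(q), n)
  if (any(pi <= 0) || any(pi > 1)) stop_ivcalib("ivcalib_config_error", "inclusion probabilities must lie in (0, 1]")
  if (any(q <= 0)) stop_ivcalib("ivcalib_config_error", "q factors must be positive")
  ord <- order(indices)
  structure(list(indices = indices[ord], n = n, N = as.integer(N),
                 pi = pi[ord], d = 1 / pi[ord], q = q[ord]),
            class = "survey_sample")
}

#' @export
print.survey_sample <- function(x, ...) {
  cat(sprintf("Survey sample: n = %d of N = %d (f = %.3g); d_k in [%.4g, %.4g]\n",
              x$n, x$N, x$n / x$N, min(x$d), max(x$d)))
  invisible(x)
}

total_estimate <- function(estimate, estimator, variance = NULL, beta = NULL) {
  structure(list(estimate = as.numeric(estimate), estimator = estimator,
                 variance = if (!is.null(variance)) as.numeric(variance),
                 beta = if (!is.null(beta)) as.numeric(beta)),
            class = "total_estimate")
}

#' @export
print.total_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of t_y: %.6g", x$estimator, x$estimate))
  if (!is.null(x$variance)) cat(sprintf("  (variance %.6g)", x$variance))
  cat("\n")
  invisible(x)
}

check_alignment <- function(sample, y_s) {
  if (length(y_s) != sample$n)
    stop_ivcalib("ivcalib_alignment_error",
                 sprintf("y_s has length %d but the sample has n = %d units", length(y_s), sample$n))
  as.numeric(y_s)
}

#' Horvitz-Thompson estimator of a population total
#'
#' \eqn{\hat t_{y\pi} = \sum_s d_k y_k} with design weights \eqn{d_k = 1/\pi_k}.
#'
#' @param sample a [survey_sample()].
#' @param y_s study-variable values aligned with `sample$indices`.
#' @return A `total_estimate` with estimator tag `"HT"`.
#' @seealso [ht_variance()] for the SRSWOR variance estimator.
#' @export
ht_total <- function(sample, y_s) {
  stopifnot(inherits(sample, "survey_sample"))
  y_s <- check_alignment(sample, y_s)
  total_estimate(sum(sample$d * y_s), "HT")
}

#' SRSWOR variance estimator for the Horvitz-Thompson total
#'
#' Returns \eqn{N^2 (1 - n/N) s^2_y / n}, the closed form of the
#' \eqn{\Delta_{kl}/\pi_{kl}} double sum under SRSWOR, where \eqn{s^2_y} is
#' the sample variance of `y_s` (denominator n - 1). Joint inclusion
#' probabilities \eqn{\pi_{kl} = n(n-1)/(N(N-1))} are analytic, never stored.
#'
#' @inheritParams ht_total
#' @return Nonnegative scalar; 0 at a census or for constant `y_s`.
#' @export
ht_variance <- function(sample, y_s) {
  stopifnot(inherits(sample, "survey_sample"))
  y_s <- check_alignment(sample, y_s)
  n <- sample$n; N <- sample$N
  if (n < 2L)
    stop_ivcalib("ivcalib_undefined_variance", "the SRSWOR variance estimator requires n >= 2")
  N^2 * (1 - n / N) * stats::var(y_s) / n
}
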