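# Fixture builders shared across test files. All randomness is seeded by the
# caller so every case is reproducible in isolation.

# Small population with Gaussian auxiliaries; column 1 optionally endogenous
# in the instrument sense (z1 differs from x1 but is correlated with it).
toy_population <- function(N = 40, p = 2, seed = 1, endogenous = FALSE,
                           beta = rep(1, p), sigma_e = 1) {
  set.seed(seed)
  e <- rnorm(N, 0, sigma_e)
  X <- matrix(rnorm(N * p), N, p)
  Z <- X
  if (endogenous) {
    Z[, 1] <- rnorm(N)
    X[, 1] <- Z[, 1] + e + rnorm(N)
  }
  y <- drop(X %*% beta) + e
  finite_population(y, X, Z, endogenous_idx = if (endogenous) 1L else integer(0))
}

# Random (population, sample) instance for property loops: n in [5, 200],
# p in [1, 10] with n > p so the Gram matrices are a.s. invertible.
random_instance <- function(seed, zx_equal = FALSE) {
  set.seed(seed)
  n <- sample(5:200, 1)
  p <- sample(seq_len(min(10L, n - 1L)), 1)
  N <- n * sample(2:6, 1)
  pop <- toy_population(N = N, p = p, seed = seed + 10000L,
                        endogenous = !zx_equal && p >= 1)
  s <- draw_srswor(pop, n, seed = seed + 20000L)
  idx <- s$indices
  list(pop = pop, s = s, n = n, p = p, N = N,
       y_s = pop$y[idx],
       X_s = pop$X[idx, , drop = FALSE],
       Z_s = if (zx_equal) pop$X[idx, , drop = FALSE] else pop$Z[idx, , drop = FALSE],
       t_x = pop$t_x,
       t_xns = pop$t_x - colSums(pop$X[idx, , drop = FALSE]))
}

# Census sample over the whole population.
census_sample <- function(pop) survey_sample(seq_len(pop$N), pop$N)

# All C(N, n) SRSWOR samples of a population, as a list of index vectors.
all_samples <- function(N, n) {
  cmb <- utils::combn(N, n)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

# Independent re-computation of the relative calibration gap used in tests.
constraint_gap_of <- function(w, X_s, t_x) {
  got <- drop(crossprod(X_s, w))
  max(abs(got - t_x) / pmax(abs(t_x), 1))
}
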