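# shared helpers for oracle computations, independent of the C++ kernel

# batch-means Monte Carlo standard error for autocorrelated draws
mcse_batch <- function(x, n_batch = 40) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}

# stationary covariance of d_t for the lag-0-wired VAR(1), via a kron solve
# (independent of the package's doubling-iteration implementation)
stat_cov_kron <- function(B1, B0, Psi) {
  K <- nrow(B1)
  M0i <- solve(diag(K) - B0)
  A <- M0i %*% B1
  Q <- M0i %*% Psi %*% t(M0i)
  matrix(solve(diag(K * K) - kronecker(A, A), as.vector(Q)), K, K)
}

# joint covariance of the stacked T-slot series (slot-major, K per slot)
joint_stat_cov <- function(B1, B0, Psi, T_) {
  K <- nrow(B1)
  M0i <- solve(diag(K) - B0)
  A <- M0i %*% B1
  V <- stat_cov_kron(B1, B0, Psi)
  pow <- function(M, k) {
    R <- diag(nrow(M))
    for (i in seq_len(k)) R <- R %*% M
    R
  }
  S <- matrix(0, K * T_, K * T_)
  for (t1 in seq_len(T_)) for (t2 in seq_len(T_)) {
    blk <- if (t1 >= t2) pow(A, t1 - t2) %*% V else V %*% t(pow(A, t2 - t1))
    S[((t1 - 1) * K + 1):(t1 * K), ((t2 - 1) * K + 1):(t2 * K)] <- blk
  }
  S
}

# small gridded dataset for sampler tests (noise-free composites so the
# fitted model coincides with the generating process)
make_test_data <- function(n_persons, n_days, adherence, seed,
                           pop = population_params(), noise_sd = 0) {
  ds <- simulate_ema_dataset(pop, n_persons = n_persons,
                             design = ema_design(n_days = n_days),
                             grid = grid_spec(n_days),
                             adherence_mean = adherence, adherence_sd = 0,
                             model = item_model(noise_sd = noise_sd),
                             seed = seed)
  g <- suppressWarnings(grid_ema_dataset(ds$long, ds$grid, ds$catalog))
  list(gridded = g, ds = ds)
}

fast_mcmc <- function(iter, seed, ...) {
  mcmc_settings(min_iterations = iter, max_iterations = iter, seed = seed,
                ...)
}
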