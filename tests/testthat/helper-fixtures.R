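# shared fixture builders for the test suite

# small continuous-feature dataset with an optional product-form signal
make_continuous_instance <- function(seed, n = 30, p = 5, coef = 0.8,
                                     m = 3) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- matrix(rnorm(n, 2, 1), n, 1)
  y <- 0.4 * X[, 1] + coef * Z[, 1] * Z[, 3] + rnorm(n)
  list(data = model_data(y, X, Z),
       kernels = default_kernels(
         Z, type = "continuous",
         names = c("Linear", "Quadratic", "Gaussian")[seq_len(m)]))
}

# light optimizer configuration used for replicate-heavy checks
light_map_config <- function(seed = 1) {
  map_config(n_starts = 4, max_evals = 600, tol = 1e-4, seed = seed)
}

# light sampler configuration for desk-scale chains
light_mcmc_config <- function(seed = 1, iterations = 4000, chains = 3) {
  mcmc_config(iterations = iterations, chains = chains, seed = seed,
              aux_draws = 1500, extension_iters = 2000, max_extensions = 1)
}

# wrap a plain matrix as an (un-normalized) kernel object
new_kernel_for_test <- function(M, name = "custom") {
  bkat:::new_kernel(M, name)
}

# numerically stable log-mean-exp
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
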