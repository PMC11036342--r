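test_that("Laplace is exact for a synthetic Gaussian log-posterior", {
  # an exactly quadratic log-posterior with known normalizer C: the Laplace
  # formula must recover C to numerical precision
  set.seed(61)
  d <- 3
  A <- crossprod(matrix(rnorm(d * d), d))  # precision matrix
  mu <- c(0.3, -1, 2)
  C <- 4.7  # true log evidence
  fit <- structure(list(
    hypothesis = "H0", m = 0L, k = d - 1L,
    theta_hat = NULL, support = integer(0),
    pin_tau0 = FALSE, pin_tau2 = FALSE,
    log_posterior_at_mode = C - d / 2 * log(2 * pi) +
      0.5 * determinant(A)$modulus[1],
    hessian = A, mode_vec = mu,
    bounds = list(lower = rep(-Inf, d), upper = rep(Inf, d)),
    converged = TRUE, n_evals = 0L, at_boundary = character(0)),
    class = "bkat_map_fit")
  expect_equal(as.numeric(laplace_log_marginal(fit)), C, tolerance = 1e-6)
})

test_that("analytic beta integration matches 1-D quadrature", {
  # conjugate sub-case: sigma2 fixed, beta ~ N(0, bv): the evidence is the
  # Gaussian closed form N(y; 0, sigma2 I + bv x x') used inside the
  # reference oracle; cross-check it against direct quadrature over beta
  set.seed(62)
  n <- 10
  x <- rnorm(n, 2, 1)
  y <- 0.5 * x + rnorm(n)
  sigma2 <- 1.3
  bv <- 10
  closed <- bkat:::logmvn(y, 0, sigma2 * diag(n) + bv * tcrossprod(x))
  gl <- bkat:::gauss_legendre(300, -5, 5)
  vals <- vapply(gl$nodes, function(b)
    sum(dnorm(y, b * x, sqrt(sigma2), log = TRUE)) +
      dnorm(b, 0, sqrt(bv), log = TRUE), numeric(1))
  quad <- log(sum(gl$weights * exp(vals - max(vals)))) + max(vals)
  expect_equal(closed, quad, tolerance = 1e-8)
})

test_that("the reference oracle is self-consistent", {
  inst <- make_continuous_instance(63, m = 2)
  pri <- prior_spec()
  # doubling the quadrature/MC budget moves the estimate by less than the
  # reported uncertainty
  r1 <- reference_log_marginal(inst$data, inst$kernels, pri, "H1",
                               budget = list(n_tau = 8, n_rho = 64,
                                             seed = 1))
  r2 <- reference_log_marginal(inst$data, inst$kernels, pri, "H1",
                               budget = list(n_tau = 16, n_rho = 128,
                                             seed = 2))
  expect_lt(abs(r1 - r2),
            3 * sqrt(attr(r1, "mc_error")^2 + attr(r2, "mc_error")^2) +
              0.02)
  # H0 quadrature error is tiny
  r0 <- reference_log_marginal(inst$data, inst$kernels, pri, "H0")
  expect_lt(attr(r0, "quad_error"), 1e-6)
})

test_that("map_estimate recovers generating parameters", {
  # null data: beta recovered, tau1 pushed to the boundary
  hits_beta <- 0L
  hits_tau <- 0L
  n_rep <- 8L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config("NULL", n = 300, p = 10, seed = 100 + s)
    sim <- simulate_dataset(cfg)
    ker <- default_kernels(sim$data$Z, type = "continuous")
    fit <- map_estimate(sim$data, ker, hypothesis = "H1",
                        config = light_map_config(seed = s))
    if (all(abs(fit$theta_hat$beta - c(0.03, 0.5)) < 0.15))
      hits_beta <- hits_beta + 1L
    if (fit$theta_hat$tau1 < 0.05) hits_tau <- hits_tau + 1L
  }
  expect_gte(hits_beta, n_rep - 1L)
  expect_gte(hits_tau, ceiling(0.8 * n_rep))
})

test_that("map_estimate detects a strong kernel signal", {
  hits <- 0L
  n_rep <- 6L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config("A", n = 300, p = 10, seed = 200 + s)
    sim <- simulate_dataset(cfg)
    ker <- default_kernels(sim$data$Z, type = "continuous")
    fit <- map_estimate(sim$data, ker, hypothesis = "H1",
                        config = light_map_config(seed = s))
    if (fit$theta_hat$tau1 > 0) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("the tau1 = 0 short-circuit yields Bayes factor 0", {
  # pure-noise phenotype unrelated to Z
  set.seed(64)
  Z <- matrix(rnorm(60 * 8), 60, 8)
  X <- matrix(1, 60, 1)
  y <- rnorm(60)
  d <- model_data(y, X, Z)
  ker <- default_kernels(Z, type = "continuous")
  res <- bkat_map(d, ker, config = light_map_config(seed = 1))
  if (res$tau1_hat == 0) {
    expect_identical(res$log_bf10, -Inf)
    expect_identical(res$posterior_h1, 0)
    expect_true(res$diagnostics$short_circuit)
  }
  expect_equal(res$engine, "MAP")
  expect_lt(res$posterior_h1, 0.5)
})

test_that("bkat_map is deterministic for a fixed seed and data", {
  inst <- make_continuous_instance(65, n = 60, p = 8, coef = 0.8)
  r1 <- bkat_map(inst$data, inst$kernels,
                 config = light_map_config(seed = 7))
  r2 <- bkat_map(inst$data, inst$kernels,
                 config = light_map_config(seed = 7))
  expect_identical(r1$log_bf10, r2$log_bf10)
  expect_identical(r1$rho_hat, r2$rho_hat)
  expect_identical(r1$beta_hat, r2$beta_hat)
})

test_that("the Bayes factor assembly identity holds", {
  inst <- make_continuous_instance(66, n = 80, p = 8, coef = 1.5)
  res <- bkat_map(inst$data, inst$kernels,
                  config = light_map_config(seed = 2))
  expect_true(is.finite(res$log_bf10))  # strong signal: full BF path
  expect_equal(res$log_bf10,
               res$diagnostics$log_marginal_h1 -
                 res$diagnostics$log_marginal_h0, tolerance = 1e-12)
  expect_equal(res$posterior_h1,
               posterior_probability(res$log_bf10, 0.5),
               tolerance = 1e-12)
})

test_that("finite-difference Hessian matches an analytic quadratic", {
  A <- matrix(c(3, 1, 1, 2), 2)
  f <- function(x) -0.5 * drop(x %*% A %*% x) + x[1]
  H <- bkat:::fd_hessian(f, c(0.4, -0.2), rep(-Inf, 2), rep(Inf, 2))
  expect_equal(H, -A, tolerance = 1e-5)
  # one-sided at an active bound still recovers the curvature
  Hb <- bkat:::fd_hessian(f, c(0, -0.2), c(0, -Inf), rep(Inf, 2))
  expect_equal(Hb, -A, tolerance = 1e-3)
})
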