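test_that("rho_from_rho_tilde normalizes onto the simplex preserving ratios", {
  expect_equal(rho_from_rho_tilde(c(1, 1, 1)), rep(1 / 3, 3))
  expect_equal(rho_from_rho_tilde(c(2, 0.5, 0.5)), c(2 / 3, 1 / 6, 1 / 6))
  expect_equal(rho_from_rho_tilde(5), 1)
  expect_error(rho_from_rho_tilde(c(1, 0)), "positive")
  expect_error(rho_from_rho_tilde(c(1, -2)), "positive")
  # Gamma(1,1) inputs -> Dirichlet(1,1,1): uniform over the simplex, so
  # each component has mean 1/3 and variance 2/36 (Dirichlet moments)
  set.seed(1)
  draws <- t(replicate(4000, rho_from_rho_tilde(rgamma(3, 1, 1))))
  expect_equal(colMeans(draws), rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(apply(draws, 2, var), rep(1 / 18, 3), tolerance = 0.01)
})

test_that("log_prior sums the stated component densities", {
  pri <- prior_spec()
  th <- theta_h1(rho_tilde = c(1, 1, 1), tau1 = 1, sigma2 = 1,
                 beta = c(0, 0))
  manual <- (2 * log(2) - lgamma(2) - 3 * log(1) - 2) +  # InvGamma(2,2) at 1
    log(1 / 2) +                                          # Uniform(0,2) at 1
    2 * dnorm(0, 0, sqrt(10), log = TRUE) +               # N(0, 10) at 0
    3 * dgamma(1, 1, 1, log = TRUE)                       # Gamma(1,1) at 1
  expect_equal(log_prior(th, pri), manual, tolerance = 1e-12)

  # outside support
  th2 <- th
  th2$tau1 <- 2.5
  expect_identical(log_prior(th2, pri), -Inf)

  # widening the beta prior increases density at large effects
  th3 <- theta_h1(c(1, 1, 1), 1, 1, beta = c(8, 8))
  expect_gt(log_prior(th3, prior_spec(beta_var = 20)),
            log_prior(th3, prior_spec(beta_var = 10)))
})

test_that("log-likelihood reduces to iid normals when tau1 = 0", {
  d <- model_data(y = c(0, 0, 0), X = matrix(0, 3, 1),
                  Z = matrix(rnorm(9), 3, 3))
  th <- theta_h0(sigma2 = 1, beta = 0)
  expect_equal(log_likelihood(th, d), -(3 / 2) * log(2 * pi),
               tolerance = 1e-12)
  # nesting: H1 with tau1 = 0 equals H0 exactly for any (sigma2, beta)
  ker <- default_kernels(d$Z, type = "continuous")
  th1 <- theta_h1(c(1, 2, 3), tau1 = 0, sigma2 = 0.7, beta = 0.3)
  th0 <- theta_h0(sigma2 = 0.7, beta = 0.3)
  expect_identical(log_likelihood(th1, d, ker), log_likelihood(th0, d))
})

test_that("likelihood matches a hand-computed bivariate density with K = I", {
  # normalized identity kernel: V = sigma2 (tau1 + 1) I
  y <- c(0.5, -1.2)
  d <- model_data(y, X = matrix(1, 2, 1), Z = diag(2))
  ker <- kernel_set(normalize_kernel(new_kernel_for_test(diag(2))))
  th <- theta_h1(1, tau1 = 0.8, sigma2 = 1.3, beta = 0.2)
  v <- 1.3 * (0.8 + 1)
  manual <- sum(dnorm(y, 0.2, sqrt(v), log = TRUE))
  expect_equal(log_likelihood(th, d, ker), manual, tolerance = 1e-10)
})

test_that("eigendecomposition and Cholesky paths agree on random instances", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    d <- model_data(rnorm(n), matrix(rnorm(2 * n), n, 2),
                    matrix(rnorm(5 * n), n, 5))
    ker <- default_kernels(d$Z, type = "continuous")
    th <- theta_h1(rgamma(3, 1, 1), tau1 = runif(1, 0.05, 1.9),
                   sigma2 = runif(1, 0.3, 2), beta = rnorm(2, 0, 0.5))
    le <- log_likelihood(th, d, ker, method = "eigen")
    lc <- log_likelihood(th, d, ker, method = "chol")
    expect_equal(le, lc, tolerance = 1e-6)
    # and both agree with a dense multivariate normal evaluation
    rho <- rho_from_rho_tilde(th$rho_tilde)
    V <- th$sigma2 * (th$tau1 * composite_kernel(ker, rho)$values + diag(n))
    r <- d$y - drop(d$X %*% th$beta)
    direct <- -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
                        drop(r %*% solve(V, r)))
    expect_equal(le, direct, tolerance = 1e-6)
  }
})

test_that("log-likelihood is invariant under consistent sample permutation", {
  set.seed(12)
  n <- 25
  d <- model_data(rnorm(n), matrix(rnorm(2 * n), n, 2),
                  matrix(rnorm(4 * n), n, 4))
  ker <- default_kernels(d$Z, type = "continuous")
  th <- theta_h1(c(1, 1, 1), 0.6, 1.1, c(0.2, -0.1))
  pri <- prior_spec()
  base <- log_posterior_unnorm(th, d, ker, pri)
  perm <- sample(n)
  dp <- model_data(d$y[perm], d$X[perm, ], d$Z[perm, ])
  kerp <- default_kernels(dp$Z, type = "continuous")
  expect_equal(log_posterior_unnorm(th, dp, kerp, pri), base,
               tolerance = 1e-8)
})

test_that("doubling sigma2 changes the likelihood by the Gaussian scale term", {
  set.seed(13)
  n <- 20
  d <- model_data(rnorm(n), matrix(1, n, 1), matrix(rnorm(3 * n), n, 3))
  ker <- default_kernels(d$Z, type = "continuous")
  rho_t <- c(1, 1, 1)
  tau1 <- 0.5
  ll1 <- log_likelihood(theta_h1(rho_t, tau1, 1, 0), d, ker)
  ll2 <- log_likelihood(theta_h1(rho_t, tau1, 2, 0), d, ker)
  # V2 = 2 V1, residual r fixed: difference = -n/2 log 2 - (q/2)(1/2 - 1)
  rho <- rho_from_rho_tilde(rho_t)
  V1 <- tau1 * composite_kernel(ker, rho)$values + diag(n)
  q <- drop(d$y %*% solve(V1, d$y))
  expect_equal(ll2 - ll1, -n / 2 * log(2) + q / 4, tolerance = 1e-8)
})

test_that("log_posterior_unnorm is likelihood plus prior, -Inf off support", {
  set.seed(14)
  d <- model_data(rnorm(10), matrix(1, 10, 1), matrix(rnorm(30), 10, 3))
  ker <- default_kernels(d$Z, type = "continuous")
  pri <- prior_spec()
  th <- theta_h1(c(0.5, 1, 2), 0.4, 0.9, 0.1)
  expect_equal(log_posterior_unnorm(th, d, ker, pri),
               log_likelihood(th, d, ker) + log_prior(th, pri),
               tolerance = 1e-12)
  th$tau1 <- 3
  class(th) <- "bkat_theta_h1"
  expect_identical(log_posterior_unnorm(th, d, ker, pri), -Inf)
})

test_that("model_data validates alignment and missingness", {
  expect_error(model_data(1, matrix(1, 1, 1), matrix(1, 1, 1)), "at least 2")
  expect_error(model_data(c(1, 2), matrix(1, 3, 1), matrix(1, 2, 1)),
               "same number of rows")
  expect_error(model_data(c(1, NA), matrix(1, 2, 1), matrix(1, 2, 1)),
               "missing")
  expect_error(model_data(c(1, 2), matrix(1, 2, 1), matrix(1, 2, 1),
                          sample_ids = c("a", "a")), "duplicate")
})
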