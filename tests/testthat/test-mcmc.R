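test_that("psrf matches the direct formula on hand-sized chains", {
  xs <- list(c(1, 2, 3, 4), c(2, 3, 4, 6))
  L <- 4
  means <- sapply(xs, mean)
  W <- mean(sapply(xs, var))
  B <- L * var(means)
  manual <- sqrt(((L - 1) / L * W + B / L) / W)
  # bypass burn-in handling by passing plain vectors
  expect_error(psrf(xs), "at least 10")
  xs10 <- lapply(xs, function(x) rep(x, length.out = 12))
  L <- 12
  means <- sapply(xs10, mean)
  W <- mean(sapply(xs10, var))
  B <- L * var(means)
  manual <- sqrt(((L - 1) / L * W + B / L) / W)
  expect_equal(psrf(xs10), manual, tolerance = 1e-12)

  # independent draws from a common normal: R-hat near 1
  set.seed(71)
  same <- replicate(3, rnorm(5000), simplify = FALSE)
  expect_gt(psrf(same), 0.99)
  expect_lt(psrf(same), 1.05)

  # far-apart chains: R-hat much larger than the convergence cutoff
  apart <- list(rnorm(500), rnorm(500) + 100)
  expect_gt(psrf(apart), 10)

  # degenerate chains
  expect_error(psrf(list(rep(1, 20), rep(1, 20))), "degenerate")
})

test_that("fixed seeds reproduce chains bit-exactly", {
  inst <- make_continuous_instance(72, n = 40, p = 5)
  cfg <- mcmc_config(iterations = 500, chains = 2, seed = 5,
                     adapt_every = 100)
  c1 <- sample_posterior(inst$data, inst$kernels, hypothesis = "H1",
                         config = cfg)
  c2 <- sample_posterior(inst$data, inst$kernels, hypothesis = "H1",
                         config = cfg)
  expect_identical(c1$chains[[1]]$draws, c2$chains[[1]]$draws)
  expect_identical(c1$chains[[2]]$log_posteriors,
                   c2$chains[[2]]$log_posteriors)
  # acceptance rates strictly inside (0, 1)
  for (ch in c1$chains) {
    expect_gt(ch$acceptance_rate, 0)
    expect_lt(ch$acceptance_rate, 1)
  }
})

test_that("H0 chains recover the semi-analytic beta posterior", {
  # oracle: beta | sigma2 is Gaussian, sigma2 is integrated by quadrature
  set.seed(73)
  n <- 40
  x <- rnorm(n, 2, 1)
  y <- 0.6 * x + rnorm(n)
  d <- model_data(y, matrix(x, n, 1), matrix(rnorm(n * 3), n, 3))
  ker <- default_kernels(d$Z, type = "continuous")
  pri <- prior_spec()
  gl <- bkat:::gauss_legendre(80, -6, 4)  # nodes in log sigma2
  xx <- sum(x * x)
  xy <- sum(x * y)
  comp <- sapply(gl$nodes, function(u) {
    s2 <- exp(u)
    vb <- 1 / (xx / s2 + 1 / pri$beta_var)
    mb <- vb * xy / s2
    lw <- bkat:::logmvn(y, 0, s2 * diag(n) +
                          pri$beta_var * tcrossprod(x)) +
      bkat:::dinvgamma_log(s2, 2, 2) + u
    c(lw = lw, mb = mb, vb = vb)
  })
  w <- exp(comp["lw", ] - max(comp["lw", ])) * gl$weights
  w <- w / sum(w)
  mean_beta <- sum(w * comp["mb", ])
  var_beta <- sum(w * (comp["vb", ] + comp["mb", ]^2)) - mean_beta^2

  ch <- sample_posterior(d, ker, pri, "H0",
                         mcmc_config(iterations = 8000, chains = 2,
                                     seed = 11, adapt_every = 250))
  post <- do.call(rbind, bkat:::post_burnin(ch))
  beta_draws <- post[, 2]
  se <- sd(beta_draws) / sqrt(length(beta_draws) / 20)  # conservative ESS
  expect_lt(abs(mean(beta_draws) - mean_beta), 4 * se)
  expect_equal(sd(beta_draws), sqrt(var_beta), tolerance = 0.15)
})

test_that("chib marginal likelihood agrees with the reference oracle", {
  inst <- make_continuous_instance(74, n = 30, p = 5, m = 2)
  pri <- prior_spec()
  cfg <- light_mcmc_config(seed = 3, iterations = 6000)
  ch0 <- sample_posterior(inst$data, inst$kernels, pri, "H0", cfg)
  chib0 <- chib_log_marginal(ch0, inst$data, inst$kernels, pri)
  ref0 <- reference_log_marginal(inst$data, inst$kernels, pri, "H0")
  expect_lt(abs(as.numeric(chib0) - as.numeric(ref0)),
            3 * attr(chib0, "mc_error") + 0.1)

  ch1 <- sample_posterior(inst$data, inst$kernels, pri, "H1", cfg)
  chib1 <- chib_log_marginal(ch1, inst$data, inst$kernels, pri)
  ref1 <- reference_log_marginal(inst$data, inst$kernels, pri, "H1",
                                 budget = list(n_tau = 12, n_rho = 64,
                                               seed = 4))
  tol <- 3 * sqrt(attr(chib1, "mc_error")^2 + attr(ref1, "mc_error")^2)
  expect_lt(abs(as.numeric(chib1) - as.numeric(ref1)), max(tol, 0.5))

  # invariance to the choice of theta* among top posterior draws
  chib1b <- chib_log_marginal(ch1, inst$data, inst$kernels, pri,
                              star_rank = 5L)
  tol2 <- 3 * sqrt(attr(chib1, "mc_error")^2 + attr(chib1b, "mc_error")^2)
  expect_lt(abs(as.numeric(chib1) - as.numeric(chib1b)), max(tol2, 0.25))
})

test_that("H0 chain marginals match the quadrature posterior (stationarity)", {
  # bin the sampled sigma2 draws against the quadrature posterior cdf
  set.seed(75)
  n <- 50
  x <- rnorm(n, 2, 1)
  y <- 0.3 * x + rnorm(n, 0, 1)
  d <- model_data(y, matrix(x, n, 1), matrix(rnorm(n * 2), n, 2))
  ker <- default_kernels(d$Z, type = "continuous")
  pri <- prior_spec()
  ch <- sample_posterior(d, ker, pri, "H0",
                         mcmc_config(iterations = 10000, chains = 2,
                                     seed = 21, adapt_every = 250))
  post <- do.call(rbind, bkat:::post_burnin(ch))
  # thin to roughly independent draws before a nominal chi-square test
  post <- post[seq(1, nrow(post), by = 25), , drop = FALSE]
  s2_draws <- exp(post[, 1])
  # unnormalized posterior density of sigma2 on a grid
  grid <- seq(quantile(s2_draws, 0.001), quantile(s2_draws, 0.999),
              length.out = 400)
  lw <- vapply(grid, function(s2)
    bkat:::logmvn(y, 0, s2 * diag(n) + pri$beta_var * tcrossprod(x)) +
      bkat:::dinvgamma_log(s2, 2, 2), numeric(1))
  dens <- exp(lw - max(lw))
  cdf <- cumsum(dens) / sum(dens)
  qs <- sapply(c(0.2, 0.4, 0.6, 0.8), function(p)
    grid[which.min(abs(cdf - p))])
  counts <- table(cut(s2_draws, breaks = c(-Inf, qs, Inf)))
  expect_gt(chisq.test(counts, p = rep(0.2, 5))$p.value, 0.01)
})

test_that("bkat_mcmc produces a complete result with diagnostics", {
  inst <- make_continuous_instance(76, n = 40, p = 5, coef = 1)
  cfg <- light_mcmc_config(seed = 9, iterations = 3000, chains = 2)
  res <- bkat_mcmc(inst$data, inst$kernels, config = cfg)
  expect_equal(res$engine, "MCMC")
  expect_true(res$posterior_h1 >= 0 && res$posterior_h1 <= 1)
  expect_equal(sum(res$rho_hat), 1, tolerance = 1e-8)
  expect_true(res$tau1_hat >= 0 && res$tau1_hat <= 2)
  expect_true(is.finite(res$diagnostics$psrf_max_h1))
  expect_equal(res$log_bf10,
               res$diagnostics$log_marginal_h1 -
                 res$diagnostics$log_marginal_h0, tolerance = 1e-12)
  # determinism
  res2 <- bkat_mcmc(inst$data, inst$kernels, config = cfg)
  expect_identical(res$log_bf10, res2$log_bf10)
  expect_identical(res$rho_hat, res2$rho_hat)
})

test_that("chain dumps are delimited text with one row per draw", {
  inst <- make_continuous_instance(77, n = 30, p = 4)
  ch <- sample_posterior(inst$data, inst$kernels, hypothesis = "H0",
                         config = mcmc_config(iterations = 200, chains = 2,
                                              seed = 1, adapt_every = 50))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_chains(ch, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 400)
  expect_true(all(c("iteration", "chain", "log_posterior") %in% names(tab)))
})
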