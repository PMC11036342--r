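test_that("continuous features have the AR(1) correlation structure", {
  Z <- simulate_continuous_features(4000, 6, r = 0.6, seed = 1)
  # R(1,3) = 0.6^2 = 0.36
  expect_lt(abs(cor(Z[, 1], Z[, 3]) - 0.36), 0.05)
  expect_lt(abs(cor(Z[, 1], Z[, 2]) - 0.6), 0.05)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 0.05)
  # r = 0: features essentially uncorrelated
  Z0 <- simulate_continuous_features(2000, 5, r = 0, seed = 2)
  cors <- cor(Z0)[upper.tri(diag(5))]
  expect_lt(max(abs(cors)), 0.1)
  # seeded reproducibility
  expect_identical(simulate_continuous_features(50, 4, 0.6, seed = 9),
                   simulate_continuous_features(50, 4, 0.6, seed = 9))
  expect_error(simulate_continuous_features(10, 4, r = 1), "r must be")
})

test_that("genotype simulator respects allele frequencies and LD decay", {
  G <- simulate_genotypes(5000, 12, r = 0.8, maf = 0.3, seed = 3)
  expect_true(all(G %in% c(0, 1, 2)))
  freqs <- colMeans(G) / 2
  expect_true(all(freqs > 0.27 & freqs < 0.33))
  # LD decays with distance
  adj <- mean(abs(diag(cor(G)[-1, -12])))        # lag-1 pairs
  far <- mean(abs(cor(G)[cbind(1:2, 11:12)]))    # lag-10 pairs
  expect_gt(adj, far)
  expect_error(simulate_genotypes(10, 3, maf = c(0.3, 0.6, 0.2)),
               "entry 2")
  expect_identical(simulate_genotypes(40, 5, seed = 4),
                   simulate_genotypes(40, 5, seed = 4))
})

test_that("covariates are Bernoulli(0.6) and N(2, 1)", {
  X <- simulate_covariates(10000, seed = 5)
  expect_true(all(X[, 1] %in% c(0, 1)))
  expect_equal(mean(X[, 1]), 0.6, tolerance = 0.02)
  expect_equal(mean(X[, 2]), 2, tolerance = 0.06)
  expect_equal(sd(X[, 2]), 1, tolerance = 0.05)
  expect_identical(simulate_covariates(10, seed = 6),
                   simulate_covariates(10, seed = 6))
})

test_that("scenario functions evaluate to their defining formulas", {
  Z <- matrix(0, 2, 3)
  Z[1, ] <- c(1, 0, 2)    # Z1 = 1, Z3 = 2
  expect_equal(scenario_h(Z, "A")[1], 1.2)
  expect_equal(scenario_h(Z, "B")[1], 0.55 * 2 + 0.1 * 1 + 0.1 * 2)
  expect_equal(scenario_h(Z, "C")[2], 1.5)   # Z1 = Z3 = 0
  expect_equal(scenario_h(Z, "D")[1], 4)
  expect_equal(scenario_h(Z, "E")[1], 4 + 0.04 * 1 + 0.04 * 2)
  expect_equal(scenario_h(Z, "F")[2], 0.4)
  expect_equal(scenario_h(Z, "NULL"), c(0, 0))
  # scenario E linear column is exposed
  expect_equal(scenario_h(Z, "E", e_linear_index = 3)[1],
               4 + 0.04 * 2 + 0.04 * 2)
  # effect multiplier scales h
  expect_equal(scenario_h(Z, "A", effect = 0.5)[1], 0.6)
  expect_error(scenario_h(Z, "Q"), "unknown scenario")
  expect_error(scenario_h(Z[, 1:2, drop = FALSE], "A"), "3 feature")
})

test_that("phenotypes follow y = X beta + h + noise", {
  set.seed(7)
  Z <- matrix(rnorm(60), 20, 3)
  X <- cbind(rbinom(20, 1, 0.6), rnorm(20, 2, 1))
  beta <- c(0.03, 0.5)
  # noiseless limit
  ph <- simulate_phenotype(Z, X, beta, "A", sigma2 = 0, seed = 8)
  expect_equal(ph$y, drop(X %*% beta) + 0.6 * Z[, 1] * Z[, 3],
               tolerance = 1e-12)
  expect_equal(ph$true_h, 0.6 * Z[, 1] * Z[, 3])
  # null scenario, beta 0: variance is sigma2
  Zb <- matrix(rnorm(3 * 5000), 5000, 3)
  Xb <- matrix(0, 5000, 1)
  phb <- simulate_phenotype(Zb, Xb, 0, "NULL", sigma2 = 1, seed = 9)
  expect_gt(var(phb$y), 0.9)
  expect_lt(var(phb$y), 1.1)
  expect_error(simulate_phenotype(Z, X[1:5, ], beta, "A"), "mismatch")
})

test_that("simulate_dataset is a pure function of its configuration", {
  cfg <- simulation_config("B", n = 40, p = 10, r = 0.6, seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$data$Z, s2$data$Z)
  expect_equal(dim(s1$data$Z), c(40, 10))
  expect_equal(ncol(s1$data$X), 2)
  # genotype mode
  cfg_g <- simulation_config("D", n = 30, p = 8, r = 0.8, maf = 0.25,
                             seed = 22, feature_type = "genotype")
  sg <- simulate_dataset(cfg_g)
  expect_true(all(sg$data$Z %in% c(0, 1, 2)))
  # effect multiplier 0 equals the null scenario signal
  cfg0 <- simulation_config("A", n = 30, p = 5, seed = 23, effect = 0)
  expect_equal(simulate_dataset(cfg0)$true_h, rep(0, 30))
})

test_that("signal scaling is monotone in the effect multiplier", {
  cfgs <- lapply(c(0, 0.5, 1), function(e)
    simulation_config("A", n = 400, p = 10, seed = 31, effect = e))
  snr <- vapply(cfgs, function(cfg) {
    s <- simulate_dataset(cfg)
    var(s$true_h)
  }, numeric(1))
  expect_true(all(diff(snr) >= 0))
})
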