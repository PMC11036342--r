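#' Synthetic data generation
#'
#' Generators reproducing the simulation designs used to benchmark the
#' method: continuous features from a zero-mean multivariate normal with
#' AR(1) correlation, LD-structured discrete genotypes from a
#' latent-Gaussian threshold model, Bernoulli/normal covariates, and
#' phenotypes y = X beta + h(Z) + eps with scenario functions A-F and
#' N(0, sigma2) noise.  Every generator is a pure function of its arguments
#' and seed.
#'
#' @name simulate
NULL

#' Simulation configuration
#'
#' Defaults follow the continuous-feature benchmark design: n = 500
#' individuals, p = 100 features with AR(1) correlation r = 0.6, two
#' covariates with coefficients beta = (0.03, 0.5), noise variance
#' sigma2 = 1.
#'
#' @param scenario one of "A".."F" or "NULL" (h = 0).
#' @param n sample size.
#' @param p feature count (scenario functions use columns 1 and 3, so
#'   p >= 3).
#' @param r AR(1) correlation between adjacent features, in [0, 1).
#' @param beta covariate coefficients (length 2 by default).
#' @param sigma2 noise variance.
#' @param maf minor allele frequencies for genotype mode (scalar or length
#'   p; default 0.3).
#' @param seed integer seed.
#' @param feature_type "continuous" or "genotype".
#' @param effect multiplier applied to h(Z) (1 = the scenario as defined;
#'   0 = null).
#' @return An object of class \code{bkat_sim_config}.
#' @export
simulation_config <- function(scenario = "A", n = 500L, p = 100L, r = 0.6,
                              beta = c(0.03, 0.5), sigma2 = 1,
                              maf = 0.3, seed = 1L,
                              feature_type = c("continuous", "genotype"),
                              effect = 1) {
  scenario <- match.arg(scenario, c("A", "B", "C", "D", "E", "F", "NULL"))
  feature_type <- match.arg(feature_type)
  if (p < 3L) stop("simulation_config: scenario functions need p >= 3")
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 r = r, beta = beta, sigma2 = sigma2, maf = maf,
                 seed = as.integer(seed), feature_type = feature_type,
                 effect = effect),
            class = "bkat_sim_config")
}

# n x p matrix of N(0,1) variables with AR(1) cross-column correlation,
# built by the exact recursion Z_j = r Z_{j-1} + sqrt(1-r^2) e_j
ar1_normal <- function(n, p, r) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (r != 0 && p > 1)
    for (j in 2:p) Z[, j] <- r * Z[, j - 1] + sqrt(1 - r^2) * Z[, j]
  Z
}

#' Continuous features from an AR(1) multivariate normal
#'
#' Rows are iid MVN(0, R) with R(j, j') = r^|j - j'|.
#'
#' @param n,p dimensions.
#' @param r AR(1) correlation in [0, 1).
#' @param seed integer seed.
#' @return An n x p numeric matrix.
#' @export
simulate_continuous_features <- function(n, p, r = 0.6, seed = 1L) {
  if (r < 0 || r >= 1)
    stop("simulate_continuous_features: r must be in [0, 1)")
  set.seed(seed)
  ar1_normal(n, p, r)
}

#' LD-structured genotypes from a latent-Gaussian threshold model
#'
#' Two independent latent AR(1) normal haplotype draws per individual are
#' thresholded at the maf-quantile into alleles and summed into a 0/1/2
#' genotype, so the marginal allele frequency matches \code{maf} and the
#' linkage disequilibrium between SNPs decays with distance.  This is a
#' synthetic stand-in for LD-preserving resampling of real genotype panels.
#'
#' @param n,p dimensions.
#' @param r latent AR(1) correlation controlling LD strength.
#' @param maf minor allele frequency, scalar or length-p vector in (0, 0.5].
#' @param seed integer seed.
#' @return An n x p integer matrix with entries in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, p, r = 0.8, maf = 0.3, seed = 1L) {
  if (r < 0 || r >= 1) stop("simulate_genotypes: r must be in [0, 1)")
  maf <- rep_len(maf, p)
  bad <- which(maf <= 0 | maf > 0.5)
  if (length(bad))
    stop("simulate_genotypes: maf entry ", bad[1], " (", maf[bad[1]],
         ") outside (0, 0.5]")
  set.seed(seed)
  thr <- stats::qnorm(maf)
  h1 <- sweep(ar1_normal(n, p, r), 2, thr, `<`)
  h2 <- sweep(ar1_normal(n, p, r), 2, thr, `<`)
  G <- h1 + h2
  storage.mode(G) <- "double"
  G
}

#' Covariates: one Bernoulli(0.6) binary and one N(2, 1) continuous
#'
#' @param n sample size.
#' @param seed integer seed.
#' @return An n x 2 numeric matrix.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  cbind(binary = stats::rbinom(n, 1, 0.6),
        continuous = stats::rnorm(n, 2, 1))
}

#' Scenario functions h(Z)
#'
#' Feature columns are indexed 1-based (Z1 is the first column).  The
#' continuous-feature scenarios are
#' A: 0.6 Z1 Z3; B: 0.55 Z1 Z3 + 0.1 Z1 + 0.1 Z3;
#' C: 0.3 (Z1 - Z3) + 1.5 cos(Z3) exp(-Z3^2 / 5);
#' and the genotype scenarios
#' D: 2 Z1 Z3; E: 2 Z1 Z3 + 0.04 Zi + 0.04 Z3 (the linear column i defaults
#' to 1 and is exposed as an argument); F: 0.4 (Z1 - Z3) +
#' 0.4 cos(Z3) exp(-Z3^2 / 5).  "NULL" is h = 0.
#'
#' @param Z feature matrix with at least 3 columns.
#' @param scenario scenario id.
#' @param effect multiplier on h.
#' @param e_linear_index column used for the linear term of scenario E.
#' @return Numeric vector of length nrow(Z).
#' @export
scenario_h <- function(Z, scenario, effect = 1, e_linear_index = 1L) {
  if (scenario != "NULL" && ncol(Z) < 3L)
    stop("scenario_h: scenario functions need at least 3 feature columns")
  z1 <- if (ncol(Z) >= 1) Z[, 1] else NULL
  z3 <- if (ncol(Z) >= 3) Z[, 3] else NULL
  h <- switch(scenario,
    A = 0.6 * z1 * z3,
    B = 0.55 * z1 * z3 + 0.1 * z1 + 0.1 * z3,
    C = 0.3 * (z1 - z3) + 1.5 * cos(z3) * exp(-z3^2 / 5),
    D = 2 * z1 * z3,
    E = 2 * z1 * z3 + 0.04 * Z[, e_linear_index] + 0.04 * z3,
    F = 0.4 * (z1 - z3) + 0.4 * cos(z3) * exp(-z3^2 / 5),
    "NULL" = rep(0, nrow(Z)),
    stop("scenario_h: unknown scenario '", scenario, "'"))
  effect * h
}

#' Simulate phenotypes from features and covariates
#'
#' y = X beta + effect * h(Z) + eps with eps iid N(0, sigma2).
#'
#' @param Z feature matrix.
#' @param X covariate matrix.
#' @param beta covariate coefficients.
#' @param scenario scenario id for h.
#' @param sigma2 noise variance.
#' @param seed integer seed (for the noise only).
#' @param effect multiplier on h(Z).
#' @return A list with \code{y} and \code{true_h}.
#' @export
simulate_phenotype <- function(Z, X, beta, scenario = "NULL", sigma2 = 1,
                               seed = 1L, effect = 1) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(Z)) stop("simulate_phenotype: Z/X row mismatch")
  if (ncol(X) != length(beta))
    stop("simulate_phenotype: length(beta) != ncol(X)")
  h <- scenario_h(Z, scenario, effect = effect)
  set.seed(seed)
  eps <- if (sigma2 > 0) stats::rnorm(nrow(Z), 0, sqrt(sigma2)) else 0
  list(y = drop(X %*% beta) + h + eps, true_h = h)
}

#' Simulate a complete dataset from a configuration
#'
#' Draws features (continuous AR(1) or LD-structured genotypes), covariates
#' and phenotype, each from a sub-seed derived from \code{config$seed}, and
#' returns an analysis-ready \code{\link{model_data}} plus the generating
#' truth.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list of class \code{bkat_sim_data}: \code{data}
#'   (\code{bkat_data}), \code{true_h}, \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "bkat_sim_config"))
  s <- config$seed
  Z <- if (config$feature_type == "continuous")
    simulate_continuous_features(config$n, config$p, config$r, seed = s)
  else simulate_genotypes(config$n, config$p, config$r, config$maf, seed = s)
  X <- simulate_covariates(config$n, seed = s + 1000003L)
  ph <- simulate_phenotype(Z, X, config$beta, config$scenario,
                           config$sigma2, seed = s + 2000003L,
                           effect = config$effect)
  structure(list(data = model_data(ph$y, X, Z), true_h = ph$true_h,
                 config = config),
            class = "bkat_sim_data")
}

#' Write a simulated dataset to delimited files
#'
#' Writes the feature matrix, covariates and phenotype in the same
#' tab-separated layouts the readers consume, plus a JSON manifest with the
#' generating configuration.
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- sim$data
  # %.17g guarantees that doubles survive the write -> read round trip
  fmt <- function(df) {
    for (nm in names(df))
      if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
    df
  }
  gt <- data.frame(sample_id = d$sample_ids, d$Z, check.names = FALSE)
  names(gt)[-1] <- d$feature_ids
  utils::write.table(fmt(gt), file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cov <- data.frame(sample_id = d$sample_ids, d$X, check.names = FALSE)
  utils::write.table(fmt(cov), file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample_id = d$sample_ids, phenotype = d$y)
  utils::write.table(fmt(ph), file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
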