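#' Weakly informative prior specification
#'
#' Defaults: sigma2 ~ Inverse-Gamma(2, 2) (shape-scale convention, density
#' proportional to x^-(a+1) exp(-b/x)); tau1 ~ Uniform(0, 2); beta ~
#' N(0, 10 I); each unscaled kernel weight rho_tilde_i ~ Gamma(1, 1), which
#' makes the normalized weights rho Dirichlet(1, ..., 1) on the simplex.
#' \code{prior_h1} is the prior probability of association P(H1).
#'
#' @param sigma2_shape,sigma2_scale Inverse-Gamma hyperparameters for sigma2.
#' @param tau1_low,tau1_high support of the uniform prior on tau1.
#' @param beta_var variance of the isotropic normal prior on beta.
#' @param rho_tilde_shape,rho_tilde_rate Gamma hyperparameters for rho_tilde.
#' @param prior_h1 prior probability of H1, in (0, 1).
#' @return An object of class \code{bkat_priors}.
#' @export
prior_spec <- function(sigma2_shape = 2, sigma2_scale = 2,
                       tau1_low = 0, tau1_high = 2,
                       beta_var = 10,
                       rho_tilde_shape = 1, rho_tilde_rate = 1,
                       prior_h1 = 0.5) {
  stopifnot(sigma2_shape > 0, sigma2_scale > 0, beta_var > 0,
            rho_tilde_shape > 0, rho_tilde_rate > 0,
            tau1_high > tau1_low, tau1_low >= 0,
            prior_h1 > 0, prior_h1 < 1)
  structure(list(sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale,
                 tau1_low = tau1_low, tau1_high = tau1_high,
                 beta_var = beta_var,
                 rho_tilde_shape = rho_tilde_shape,
                 rho_tilde_rate = rho_tilde_rate,
                 prior_h1 = prior_h1),
            class = "bkat_priors")
}

#' Normalize unscaled kernel weights onto the simplex
#'
#' rho = rho_tilde / sum(rho_tilde).  With iid Gamma(1,1) inputs the output
#' is Dirichlet(1, ..., 1) distributed.
#'
#' @param rho_tilde vector of positive unscaled weights.
#' @return Simplex vector of the same length (sums to 1).
#' @export
rho_from_rho_tilde <- function(rho_tilde) {
  rho_tilde <- as.numeric(rho_tilde)
  if (!length(rho_tilde) || any(!is.finite(rho_tilde)) || any(rho_tilde <= 0))
    stop("rho_from_rho_tilde: entries must be positive and finite")
  rho_tilde / sum(rho_tilde)
}

# log density of Inverse-Gamma(shape a, scale b) at x
dinvgamma_log <- function(x, a, b) {
  ifelse(x > 0, a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x, -Inf)
}

#' Log prior density of a parameter vector
#'
#' Sum of the independent log prior densities of the components of
#' \code{theta} under the given hypothesis; returns \code{-Inf} outside the
#' support (never errors).
#'
#' @param theta a \code{\link{theta_h1}} or \code{\link{theta_h0}} object.
#' @param priors a \code{\link{prior_spec}}.
#' @param hypothesis \code{"H1"} or \code{"H0"} (default inferred from the
#'   class of \code{theta}).
#' @return Scalar log density.
#' @export
log_prior <- function(theta, priors = prior_spec(), hypothesis = NULL) {
  if (is.null(hypothesis))
    hypothesis <- if (inherits(theta, "bkat_theta_h1")) "H1" else "H0"
  hypothesis <- match.arg(hypothesis, c("H1", "H0"))
  lp <- dinvgamma_log(theta$sigma2, priors$sigma2_shape, priors$sigma2_scale) +
    sum(stats::dnorm(theta$beta, 0, sqrt(priors$beta_var), log = TRUE))
  if (hypothesis == "H1") {
    lp <- lp +
      stats::dunif(theta$tau1, priors$tau1_low, priors$tau1_high, log = TRUE) +
      sum(stats::dgamma(theta$rho_tilde, shape = priors$rho_tilde_shape,
                        rate = priors$rho_tilde_rate, log = TRUE))
  }
  as.numeric(lp)
}

# log Dirichlet(1,...,1) density of the simplex weights: constant lgamma(m).
# Used by the MAP engine, which works with rho directly (the Gamma(1,1)
# prior on rho_tilde marginalizes exactly to Dirichlet(1,...,1) on rho, and
# the likelihood depends on rho only).
ddirichlet1_log <- function(m) lgamma(m)

# draw a parameter vector from the prior (used for multistarts / chain inits)
draw_prior_theta <- function(priors, hypothesis, m, k) {
  sigma2 <- 1 / stats::rgamma(1, shape = priors$sigma2_shape,
                              rate = priors$sigma2_scale)
  beta <- stats::rnorm(k, 0, sqrt(priors$beta_var))
  if (hypothesis == "H0") return(theta_h0(sigma2, beta))
  theta_h1(
    rho_tilde = stats::rgamma(m, shape = priors$rho_tilde_shape,
                              rate = priors$rho_tilde_rate),
    tau1 = stats::runif(1, priors$tau1_low, priors$tau1_high),
    sigma2 = sigma2, beta = beta)
}
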