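#' Model log-likelihood and unnormalized log-posterior
#'
#' The kernel machine regression model y = X beta + h(Z) + eps with
#' h ~ N(0, tau K_c) and eps ~ N(0, sigma2 I) is equivalent to the marginal
#' data distribution y | theta ~ N(X beta, sigma2 (tau1 K_c + I)) with
#' tau1 = tau / sigma2.  Under H0 (tau1 = 0) the kernel term vanishes and
#' the likelihood reduces to iid normal errors.
#'
#' @name model_likelihood
NULL

# dense multivariate normal log density at y with mean mu and covariance V
logmvn <- function(y, mu, V) {
  n <- length(y)
  C <- tryCatch(chol(V), error = function(e) chol(V + 1e-8 * diag(n)))
  w <- backsolve(C, y - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(C))) - 0.5 * sum(w * w)
}

# core H1 likelihood given precomputed composite kernel values (plain matrix)
ll_h1_core <- function(y, X, beta, sigma2, tau1, Kc,
                       method = c("chol", "eigen")) {
  method <- match.arg(method)
  n <- length(y)
  r <- y - drop(X %*% beta)
  if (tau1 == 0) {
    q <- sum(r * r)
    return(-0.5 * n * log(2 * pi * sigma2) - q / (2 * sigma2))
  }
  if (method == "eigen") {
    e <- eigen(Kc, symmetric = TRUE)
    lam <- e$values
    lam[lam < max(lam) * 1e-10] <- 0        # normalized kernels can be
    lam[lam < 0] <- 0                        # numerically rank-deficient
    d <- tau1 * lam + 1
    rt <- crossprod(e$vectors, r)
    ld <- sum(log(d))
    q <- sum(rt^2 / d)
  } else {
    V <- tau1 * Kc
    diag(V) <- diag(V) + 1
    C <- tryCatch(chol(V), error = function(e2) {
      diag(V) <- diag(V) + 1e-8
      tryCatch(chol(V), error = function(e3)
        stop("log_likelihood: covariance not positive definite after jitter ",
             "(tau1 = ", tau1, ")"))
    })
    ld <- 2 * sum(log(diag(C)))
    w <- backsolve(C, r, transpose = TRUE)
    q <- sum(w * w)
  }
  -0.5 * n * log(2 * pi * sigma2) - 0.5 * ld - q / (2 * sigma2)
}

#' Log-likelihood of the kernel machine model
#'
#' Evaluates log N(y; X beta, sigma2 (tau1 K_c + I)).  The default path
#' eigendecomposes the composite kernel, so that for a fixed rho the log
#' determinant and quadratic form are cheap functions of (tau1, sigma2,
#' beta); \code{method = "chol"} instead Cholesky-factorizes the covariance
#' directly, which is faster when rho changes at every call (as it does
#' inside the joint optimizer and sampler).  Both paths agree to numerical
#' tolerance.
#'
#' @param theta a \code{\link{theta_h1}} or \code{\link{theta_h0}}.
#' @param data a \code{\link{model_data}}.
#' @param kernels a \code{\link{kernel_set}} of normalized candidates
#'   (ignored under H0).
#' @param method \code{"eigen"} (default) or \code{"chol"}.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(theta, data, kernels = NULL,
                           method = c("eigen", "chol")) {
  method <- match.arg(method)
  if (inherits(theta, "bkat_theta_h0"))
    return(ll_h1_core(data$y, data$X, theta$beta, theta$sigma2, 0, NULL))
  if (theta$tau1 == 0)
    return(ll_h1_core(data$y, data$X, theta$beta, theta$sigma2, 0, NULL))
  if (is.null(kernels))
    stop("log_likelihood: kernels required under H1 with tau1 > 0")
  rho <- rho_from_rho_tilde(theta$rho_tilde)
  Kc <- composite_kernel_values(kernels, rho)
  ll_h1_core(data$y, data$X, theta$beta, theta$sigma2, theta$tau1, Kc,
             method = method)
}

#' Unnormalized log-posterior log p(y | theta) + log pi(theta)
#'
#' @inheritParams log_likelihood
#' @param priors a \code{\link{prior_spec}}.
#' @param hypothesis \code{"H1"} or \code{"H0"} (default from theta class).
#' @return Scalar; \code{-Inf} outside the prior support.
#' @export
log_posterior_unnorm <- function(theta, data, kernels = NULL,
                                 priors = prior_spec(), hypothesis = NULL,
                                 method = c("eigen", "chol")) {
  lp <- log_prior(theta, priors, hypothesis)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(theta, data, kernels, method = match.arg(method))
}
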