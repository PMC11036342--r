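#' MCMC inference engine
#'
#' Adaptive Metropolis-Hastings sampling of the posterior under H1 and H0,
#' Gelman-Rubin convergence diagnostics, and Chib-style marginal likelihood
#' estimation from the MCMC output.  Sampling happens on an unconstrained
#' scale (log rho_tilde, scaled-logit tau1, log sigma2, beta) with the log
#' Jacobian added, so the chains target the correct posterior.
#'
#' @name inference_mcmc
NULL

#' Sampler configuration
#'
#' @param iterations iterations per chain (default 50 000).
#' @param chains number of chains (default 3).
#' @param burn_in fraction of each chain discarded (default 0.5).
#' @param adapt_every proposal-covariance update interval (iterations).
#' @param adapt_until fraction of the run after which adaptation freezes.
#' @param seed integer seed (chain c uses seed + c - 1).
#' @param aux_draws auxiliary proposal draws for the Chib-Jeliazkov
#'   posterior ordinate.
#' @param psrf_threshold convergence cutoff on the maximum PSRF.
#' @param max_extensions maximum number of chain extensions on
#'   non-convergence.
#' @param extension_iters added iterations per extension.
#' @return An object of class \code{bkat_mcmc_config}.
#' @export
mcmc_config <- function(iterations = 50000, chains = 3, burn_in = 0.5,
                        adapt_every = 500, adapt_until = 0.5, seed = 1,
                        aux_draws = 5000, psrf_threshold = 1.1,
                        max_extensions = 3, extension_iters = 25000) {
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains), burn_in = burn_in,
                 adapt_every = as.integer(adapt_every),
                 adapt_until = adapt_until, seed = as.integer(seed),
                 aux_draws = as.integer(aux_draws),
                 psrf_threshold = psrf_threshold,
                 max_extensions = as.integer(max_extensions),
                 extension_iters = as.integer(extension_iters)),
            class = "bkat_mcmc_config")
}

# ---- sampling-scale transforms (with Jacobian) -----------------------------
mcmc_par_names <- function(hypothesis, m, k, kernel_names = NULL) {
  if (hypothesis == "H0") return(c("log_sigma2", paste0("beta", seq_len(k))))
  rn <- if (is.null(kernel_names)) paste0("log_rho_tilde", seq_len(m))
        else paste0("log_rho_tilde_", kernel_names)
  c(rn, "logit_tau1", "log_sigma2", paste0("beta", seq_len(k)))
}

# log target on the sampling scale: log posterior + log |Jacobian|
make_logpost_t <- function(data, kernels, priors, hypothesis, m, k) {
  tl <- priors$tau1_low; th <- priors$tau1_high
  function(par) {
    if (hypothesis == "H0") {
      sigma2 <- exp(par[1])
      beta <- par[2:(1 + k)]
      lp <- dinvgamma_log(sigma2, priors$sigma2_shape, priors$sigma2_scale) +
        sum(stats::dnorm(beta, 0, sqrt(priors$beta_var), log = TRUE)) +
        par[1]
      if (!is.finite(lp)) return(-Inf)
      return(lp + ll_h1_core(data$y, data$X, beta, sigma2, 0, NULL))
    }
    lrt <- par[seq_len(m)]
    rho_tilde <- exp(lrt)
    t1 <- par[m + 1]
    tau1 <- tl + (th - tl) * stats::plogis(t1)
    u <- par[m + 2]
    sigma2 <- exp(u)
    beta <- par[(m + 3):(m + 2 + k)]
    lp <- sum(stats::dgamma(rho_tilde, shape = priors$rho_tilde_shape,
                            rate = priors$rho_tilde_rate, log = TRUE)) +
      -log(th - tl) +
      dinvgamma_log(sigma2, priors$sigma2_shape, priors$sigma2_scale) +
      sum(stats::dnorm(beta, 0, sqrt(priors$beta_var), log = TRUE)) +
      # Jacobians: exp for rho_tilde and sigma2, scaled logistic for tau1
      sum(lrt) + u + log(th - tl) + stats::plogis(t1, log.p = TRUE) +
      stats::plogis(-t1, log.p = TRUE)
    if (!is.finite(lp)) return(-Inf)
    rho <- rho_tilde / sum(rho_tilde)
    Kc <- composite_kernel_values(kernels, rho)
    lp + ll_h1_core(data$y, data$X, beta, sigma2, tau1, Kc, method = "chol")
  }
}

#' Draw posterior samples with adaptive Metropolis-Hastings
#'
#' Random-walk Metropolis with a Gaussian proposal whose covariance is
#' adapted from the chain history (scaled by 2.38^2/d with a small diagonal
#' regularizer) every \code{adapt_every} iterations and frozen after
#' \code{adapt_until} of the run.
#'
#' @inheritParams map_estimate
#' @param config a \code{\link{mcmc_config}}.
#' @return An object of class \code{bkat_chains}: per-chain draw matrices on
#'   the sampling scale, log-posterior values, acceptance rates, frozen
#'   proposal covariances and the seed.
#' @export
sample_posterior <- function(data, kernels, priors = prior_spec(),
                             hypothesis = c("H1", "H0"),
                             config = mcmc_config()) {
  hypothesis <- match.arg(hypothesis)
  m <- if (hypothesis == "H1") length(kernels$kernels) else 0L
  k <- ncol(data$X)
  d <- if (hypothesis == "H1") m + 2 + k else 1 + k
  logpost <- make_logpost_t(data, kernels, priors, hypothesis, m, k)
  n_iter <- config$iterations
  s2 <- 2.38^2 / d
  chains <- vector("list", config$chains)

  for (cc in seq_len(config$chains)) {
    set.seed(config$seed + cc - 1L)
    # initialize from the prior, retrying until the target is finite
    cur <- NULL
    for (try in 1:50) {
      th <- draw_prior_theta(priors, hypothesis, max(m, 1L), k)
      par0 <- if (hypothesis == "H1")
        c(log(th$rho_tilde),
          stats::qlogis((th$tau1 - priors$tau1_low) /
                          (priors$tau1_high - priors$tau1_low)),
          log(th$sigma2), th$beta)
      else c(log(th$sigma2), th$beta)
      if (is.finite(logpost(par0))) { cur <- par0; break }
    }
    if (is.null(cur))
      stop("sample_posterior: could not initialize chain ", cc)
    lp_cur <- logpost(cur)
    draws <- matrix(NA_real_, n_iter, d)
    lps <- numeric(n_iter)
    Sig <- s2 * diag(0.1, d)
    L <- chol(Sig)
    accepts <- 0L
    freeze_at <- floor(config$adapt_until * n_iter)
    for (t in seq_len(n_iter)) {
      prop <- cur + drop(crossprod(L, stats::rnorm(d)))
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp_cur) {
        cur <- prop; lp_cur <- lp_prop; accepts <- accepts + 1L
      }
      draws[t, ] <- cur
      lps[t] <- lp_cur
      if (t == 1000L && accepts == 0L)
        stop("sample_posterior: no accepted moves in the first 1000 ",
             "iterations (step-size failure)")
      if (t %% config$adapt_every == 0L && t <= freeze_at && t > 10L) {
        emp <- stats::cov(draws[seq_len(t), , drop = FALSE])
        Sig <- s2 * (emp + 1e-8 * diag(d))
        L <- tryCatch(chol(Sig), error = function(e) L)
      }
    }
    burn <- floor(config$burn_in * n_iter)
    post <- draws[(burn + 1):n_iter, , drop = FALSE]
    chains[[cc]] <- list(draws = draws, log_posteriors = lps,
                         acceptance_rate = accepts / n_iter,
                         proposal_cov = Sig,
                         seed = config$seed + cc - 1L)
  }

  structure(list(chains = chains, d = d, m = m, k = k,
                 hypothesis = hypothesis,
                 par_names = mcmc_par_names(hypothesis, m, k, kernels$names),
                 config = config, priors = priors),
            class = "bkat_chains")
}

#' @export
print.bkat_chains <- function(x, ...) {
  cat("bkat_chains (", x$hypothesis, "): ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]$draws), " iterations, d = ", x$d, "\n", sep = "")
  cat("  acceptance rates: ",
      paste(format(vapply(x$chains, `[[`, numeric(1), "acceptance_rate"),
                   digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# post-burn-in draws of one parameter across chains, as a list of vectors
post_burnin <- function(chains, parameter_index = NULL) {
  burn <- floor(chains$config$burn_in * nrow(chains$chains[[1]]$draws))
  lapply(chains$chains, function(ch) {
    m <- ch$draws[(burn + 1):nrow(ch$draws), , drop = FALSE]
    if (is.null(parameter_index)) m else m[, parameter_index]
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' R-hat = sqrt( ((L-1)/L * W + B/L) / W ) with W the mean within-chain
#' variance, B = L * var(chain means) the between-chain variance, and L the
#' post-burn-in chain length.
#'
#' @param chains a \code{\link{sample_posterior}} result (or a plain list of
#'   equal-length numeric vectors, one per chain).
#' @param parameter_index column of the draw matrices to diagnose.
#' @return Scalar R-hat.
#' @export
psrf <- function(chains, parameter_index = 1L) {
  xs <- if (inherits(chains, "bkat_chains"))
    post_burnin(chains, parameter_index) else chains
  if (length(xs) < 2L) stop("psrf: need at least 2 chains")
  L <- unique(lengths(xs))
  if (length(L) != 1L) stop("psrf: chains must have equal lengths")
  if (L < 10L) stop("psrf: need at least 10 post-burn-in draws")
  means <- vapply(xs, mean, numeric(1))
  W <- mean(vapply(xs, stats::var, numeric(1)))
  if (W == 0) stop("psrf: degenerate (constant) chains")
  B <- L * stats::var(means)
  sqrt(((L - 1) / L * W + B / L) / W)
}

max_psrf <- function(chains) {
  max(vapply(seq_len(chains$d), function(j) psrf(chains, j), numeric(1)))
}

# multivariate normal log density with covariance given by its Cholesky
dmvnorm_chol_log <- function(xmat, center, L) {
  d <- length(center)
  w <- backsolve(L, t(xmat) - center, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(L))) - 0.5 * colSums(w^2)
}

#' Chib-style log marginal likelihood from MCMC output
#'
#' Uses the identity log m(y) = log p(y | theta*) + log pi(theta*) -
#' log p(theta* | y) at the highest-posterior draw theta*, with the
#' posterior ordinate estimated by the Chib-Jeliazkov ratio: the numerator
#' averages acceptance-probability-weighted proposal densities over the
#' posterior draws, the denominator averages acceptance probabilities over
#' draws from the proposal centered at theta*.  All quantities live on the
#' sampling scale, on which the evidence is parameterization-invariant.
#'
#' @param chains a converged \code{\link{sample_posterior}} result.
#' @param data,kernels,priors the model inputs the chains were drawn for.
#' @param aux_draws number of proposal draws for the denominator.
#' @param seed seed for the auxiliary draws.
#' @param star_rank rank (by posterior density) of the draw used as
#'   theta*; 1 (default) is the highest-posterior draw.  The estimate is
#'   invariant, up to Monte Carlo error, to this choice.
#' @return Scalar log marginal likelihood with attribute \code{"mc_error"}.
#' @export
chib_log_marginal <- function(chains, data, kernels, priors = NULL,
                              aux_draws = NULL, seed = NULL,
                              star_rank = 1L) {
  if (is.null(priors)) priors <- chains$priors
  aux_draws <- aux_draws %||% chains$config$aux_draws
  seed <- seed %||% chains$config$seed
  hypothesis <- chains$hypothesis
  m <- chains$m; k <- chains$k; d <- chains$d
  logpost <- make_logpost_t(data, kernels, priors, hypothesis, m, k)

  burn <- floor(chains$config$burn_in * nrow(chains$chains[[1]]$draws))
  draws <- do.call(rbind, lapply(chains$chains, function(ch)
    ch$draws[(burn + 1):nrow(ch$draws), , drop = FALSE]))
  lps <- unlist(lapply(chains$chains, function(ch)
    ch$log_posteriors[(burn + 1):length(ch$log_posteriors)]))

  istar <- order(lps, decreasing = TRUE)[star_rank]
  theta_star <- draws[istar, ]
  lp_star <- lps[istar]

  # fixed symmetric proposal: average of the frozen per-chain covariances
  Sig <- Reduce(`+`, lapply(chains$chains, `[[`, "proposal_cov")) /
    length(chains$chains)
  L <- chol(Sig + 1e-10 * diag(d))

  # thin the posterior draws for the numerator
  keep <- seq(1, nrow(draws),
              by = max(1L, floor(nrow(draws) / 5000)))
  qd <- exp(dmvnorm_chol_log(draws[keep, , drop = FALSE], theta_star, L))
  alpha_num <- pmin(1, exp(lp_star - lps[keep]))   # = 1: theta* is the max
  num_terms <- alpha_num * qd
  num <- mean(num_terms)

  set.seed(seed + 7919L)
  Z <- matrix(stats::rnorm(aux_draws * d), aux_draws, d)
  props <- sweep(Z %*% L, 2, theta_star, `+`)
  lp_props <- apply(props, 1, logpost)
  alpha_den <- pmin(1, exp(lp_props - lp_star))
  den <- mean(alpha_den)

  if (!is.finite(num) || num <= 0 || den <= 0)
    stop("chib_log_marginal: posterior ordinate estimate is not positive ",
         "(num = ", num, ", den = ", den, ")")

  out <- lp_star - (log(num) - log(den))
  # numerator variance by batch means (the thinned posterior draws remain
  # autocorrelated); denominator draws are iid
  nb <- max(2L, min(20L, length(num_terms) %/% 10L))
  bm <- vapply(split(num_terms,
                     cut(seq_along(num_terms), nb, labels = FALSE)),
               mean, numeric(1))
  var_num <- stats::var(bm) / nb
  se <- sqrt(var_num / num^2 +
               stats::var(alpha_den) / (aux_draws * den^2))
  attr(out, "mc_error") <- se
  out
}

#' Bayes factor test with the MCMC engine
#'
#' Samples the posterior under H1 and H0, extends the H1 chains until the
#' maximum PSRF drops below the threshold (or the extension cap is hit),
#' estimates the parameters by posterior means (kernel weights are
#' normalized per draw and then averaged), computes both marginal
#' likelihoods by \code{\link{chib_log_marginal}}, and assembles the Bayes
#' factor and posterior probability of association.
#'
#' @inheritParams sample_posterior
#' @param config a \code{\link{mcmc_config}}.
#' @return A \code{bkat_result} with \code{engine = "MCMC"} and sampling
#'   diagnostics (max PSRF, acceptance rates, convergence flag, extension
#'   count, Chib standard errors).
#' @export
bkat_mcmc <- function(data, kernels, priors = prior_spec(),
                      config = mcmc_config()) {
  run_converged <- function(hypothesis) {
    cfg <- config
    n_ext <- 0L
    repeat {
      ch <- sample_posterior(data, kernels, priors, hypothesis, cfg)
      r <- max_psrf(ch)
      if (r < config$psrf_threshold || n_ext >= config$max_extensions)
        return(list(chains = ch, psrf_max = r, n_extensions = n_ext,
                    converged = r < config$psrf_threshold))
      n_ext <- n_ext + 1L
      cfg$iterations <- cfg$iterations + config$extension_iters
    }
  }

  h1 <- run_converged("H1")
  h0 <- run_converged("H0")

  m <- h1$chains$m; k <- h1$chains$k
  post <- do.call(rbind, post_burnin(h1$chains))
  rho_draws <- exp(post[, seq_len(m), drop = FALSE])
  rho_draws <- rho_draws / rowSums(rho_draws)
  rho_hat <- stats::setNames(colMeans(rho_draws), kernels$names)
  tau1_hat <- mean(h1$chains$priors$tau1_low +
                     (h1$chains$priors$tau1_high -
                        h1$chains$priors$tau1_low) *
                     stats::plogis(post[, m + 1]))
  sigma2_hat <- mean(exp(post[, m + 2]))
  beta_hat <- colMeans(post[, (m + 3):(m + 2 + k), drop = FALSE])

  lm1 <- chib_log_marginal(h1$chains, data, kernels, priors)
  lm0 <- chib_log_marginal(h0$chains, data, kernels, priors)
  log_bf10 <- as.numeric(lm1) - as.numeric(lm0)

  new_bkat_result(
    log_bf10 = log_bf10,
    posterior_h1 = posterior_probability(log_bf10, priors$prior_h1),
    rho_hat = rho_hat, tau1_hat = tau1_hat, sigma2_hat = sigma2_hat,
    beta_hat = beta_hat, engine = "MCMC",
    diagnostics = list(
      psrf_max_h1 = h1$psrf_max, psrf_max_h0 = h0$psrf_max,
      converged = h1$converged && h0$converged,
      n_extensions = h1$n_extensions + h0$n_extensions,
      acceptance_h1 = vapply(h1$chains$chains, `[[`, numeric(1),
                             "acceptance_rate"),
      acceptance_h0 = vapply(h0$chains$chains, `[[`, numeric(1),
                             "acceptance_rate"),
      log_marginal_h1 = as.numeric(lm1), log_marginal_h0 = as.numeric(lm0),
      chib_se_h1 = attr(lm1, "mc_error"), chib_se_h0 = attr(lm0, "mc_error")))
}

#' Dump chains to a delimited text file
#'
#' One row per draw: iteration, chain, the sampling-scale parameters and the
#' log-posterior; suitable for external trace-plot tooling.
#'
#' @param chains a \code{\link{sample_posterior}} result.
#' @param path output file path (tab-separated).
#' @return The path, invisibly.
#' @export
write_chains <- function(chains, path) {
  tabs <- lapply(seq_along(chains$chains), function(cc) {
    ch <- chains$chains[[cc]]
    df <- as.data.frame(ch$draws)
    names(df) <- chains$par_names
    cbind(iteration = seq_len(nrow(df)), chain = cc, df,
          log_posterior = ch$log_posteriors)
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
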