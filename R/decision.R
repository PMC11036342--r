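#' Decision rules on Bayes factors
#'
#' Converts Bayes factors to posterior probabilities of association, applies
#' the posterior-probability decision threshold, and controls the Bayesian
#' false discovery rate across many tested groups.
#'
#' @name decision_report
NULL

#' Posterior probability of association from a log Bayes factor
#'
#' P(H1 | Data) = 1 / (1 + ((1 - prior_h1) / prior_h1) / BF10), monotone
#' increasing in the Bayes factor; log BF10 = -Inf maps to 0 and +Inf to 1.
#'
#' @param log_bf10 log Bayes factor(s) in favor of association.
#' @param prior_h1 prior probability of association, in (0, 1).
#' @return Posterior probability in [0, 1], vectorized over log_bf10.
#' @export
posterior_probability <- function(log_bf10, prior_h1 = 0.5) {
  if (prior_h1 <= 0 || prior_h1 >= 1)
    stop("posterior_probability: prior_h1 must be in (0, 1)")
  ifelse(log_bf10 == Inf, 1,
         1 / (1 + (1 - prior_h1) / prior_h1 * exp(-log_bf10)))
}

# inverse: log BF10 from a posterior probability
log_bf_from_posterior <- function(posterior_h1, prior_h1 = 0.5) {
  log(posterior_h1 / (1 - posterior_h1)) - log(prior_h1 / (1 - prior_h1))
}

#' Assemble a group result table from per-group test results
#'
#' @param results named list of \code{bkat_result} objects (names are group
#'   ids).
#' @param n_features optional integer vector of group sizes.
#' @return A data.frame with one row per group: group_id, n_features,
#'   log_bf10, posterior_h1, per-kernel weight columns
#'   (\code{rho_<name>}), tau1_hat, sigma2_hat, engine, psrf_max, converged.
#' @export
group_result_table <- function(results, n_features = NA_integer_) {
  if (!length(results)) {
    warning("group_result_table: empty result list")
    return(data.frame(group_id = character(0)))
  }
  knames <- names(results[[1]]$rho_hat)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    rho <- as.list(r$rho_hat)
    names(rho) <- paste0("rho_", knames)
    psrf_max <- max(r$diagnostics$psrf_max_h1 %||% NA_real_,
                    r$diagnostics$psrf_max_h0 %||% NA_real_)
    c(list(group_id = names(results)[i] %||% as.character(i),
           n_features = if (length(n_features) > 1) n_features[i]
                        else n_features,
           log_bf10 = r$log_bf10, posterior_h1 = r$posterior_h1),
      rho,
      list(tau1_hat = r$tau1_hat, sigma2_hat = r$sigma2_hat,
           engine = r$engine, psrf_max = psrf_max,
           converged = isTRUE(r$diagnostics$converged)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Flag groups above a posterior-probability threshold
#'
#' Marks \code{selected = posterior_h1 >= threshold} (a posterior exactly at
#' the threshold counts as selected).
#'
#' @param table a data.frame with a \code{posterior_h1} column.
#' @param threshold decision threshold in (0, 1); default 0.7.
#' @return The table with a logical \code{selected} column.
#' @export
select_groups <- function(table, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1)
    stop("select_groups: threshold must be in (0, 1)")
  if (!nrow(table)) {
    warning("select_groups: empty table")
    table$selected <- logical(0)
    return(table)
  }
  table$selected <- table$posterior_h1 >= threshold
  table
}

#' Bayesian false discovery rate control across groups
#'
#' Sorts groups by decreasing posterior probability and selects the largest
#' prefix whose mean miss-probability (mean of 1 - posterior_h1 over the
#' prefix) stays at or below \code{q}; the expected false discovery
#' proportion of the returned selection is therefore at most q by
#' construction.
#'
#' @param table a data.frame with a \code{posterior_h1} column.
#' @param method only \code{"bayes_fdr"}.
#' @param q target expected FDR in (0, 1).
#' @return The table (original row order) with logical \code{selected} and
#'   numeric \code{efdr} (expected FDR of the selected set; NA for
#'   unselected rows).
#' @export
multiplicity_adjust <- function(table, method = "bayes_fdr", q = 0.05) {
  method <- match.arg(method, "bayes_fdr")
  if (q <= 0 || q >= 1)
    stop("multiplicity_adjust: q must be in (0, 1)")
  n <- nrow(table)
  table$selected <- logical(n)
  table$efdr <- NA_real_
  if (!n) return(table)
  ord <- order(table$posterior_h1, decreasing = TRUE)
  miss <- cumsum(1 - table$posterior_h1[ord]) / seq_len(n)
  kmax <- which(miss <= q)
  if (length(kmax)) {
    kmax <- max(kmax)
    sel <- ord[seq_len(kmax)]
    table$selected[sel] <- TRUE
    table$efdr[sel] <- miss[kmax]
  }
  table
}
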