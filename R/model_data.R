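#' Assemble aligned phenotype, covariate and feature matrices
#'
#' Bundles the inputs of a group-level association test: a continuous
#' phenotype vector \code{y}, a covariate matrix \code{X} and a feature
#' matrix \code{Z} (discrete 0/1/2 genotypes or continuous molecular
#' features), all aligned by sample.  No intercept is added here: include an
#' intercept column in \code{X} explicitly if one is wanted (the file readers
#' append one by default, see \code{\link{read_table}}).
#'
#' @param y numeric phenotype vector of length n.
#' @param X numeric covariate matrix (n x k).  A vector is treated as a
#'   single column.
#' @param Z numeric feature matrix (n x p).
#' @param sample_ids optional character vector of sample identifiers
#'   (default \code{"s1"..."sn"}).
#' @param feature_ids optional character vector of feature identifiers
#'   (default taken from \code{colnames(Z)} or \code{"f1"..."fp"}).
#'
#' @return An object of class \code{bkat_data}: a list with elements
#'   \code{y}, \code{X}, \code{Z}, \code{sample_ids}, \code{feature_ids}.
#' @export
model_data <- function(y, X, Z, sample_ids = NULL, feature_ids = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  storage.mode(Z) <- "double"
  n <- length(y)
  if (n < 2L)
    stop("model_data: need at least 2 samples, got ", n)
  if (nrow(X) != n || nrow(Z) != n)
    stop("model_data: y (", n, "), X (", nrow(X), ") and Z (", nrow(Z),
         ") must have the same number of rows")
  if (anyNA(y) || anyNA(X) || anyNA(Z))
    stop("model_data: missing values are not allowed; impute during ingestion")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(sample_ids) != n)
    stop("model_data: sample_ids length mismatch")
  if (anyDuplicated(sample_ids))
    stop("model_data: duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(feature_ids)) {
    feature_ids <- colnames(Z)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(Z)))
  }
  if (length(feature_ids) != ncol(Z))
    stop("model_data: feature_ids length mismatch")
  structure(
    list(y = y, X = X, Z = Z,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids)),
    class = "bkat_data")
}

#' @export
print.bkat_data <- function(x, ...) {
  cat("bkat_data: ", length(x$y), " samples, ", ncol(x$X),
      " covariates, ", ncol(x$Z), " features\n", sep = "")
  invisible(x)
}

#' Parameters of the kernel machine model under the alternative
#'
#' Under H1 the model is y ~ N(X beta, sigma2 (tau1 Kc + I)) with composite
#' kernel Kc determined by the simplex weights rho = rho_tilde / sum(rho_tilde).
#'
#' @param rho_tilde positive unscaled kernel weights (length m).
#' @param tau1 scaled variance component tau/sigma2, in [0, 2].
#' @param sigma2 positive residual variance.
#' @param beta covariate coefficient vector (length k).
#' @return An object of class \code{bkat_theta_h1}.
#' @export
theta_h1 <- function(rho_tilde, tau1, sigma2, beta) {
  rho_tilde <- as.numeric(rho_tilde)
  if (any(rho_tilde <= 0))
    stop("theta_h1: rho_tilde entries must be positive")
  if (length(tau1) != 1L || tau1 < 0 || tau1 > 2)
    stop("theta_h1: tau1 must be a scalar in [0, 2]")
  if (length(sigma2) != 1L || sigma2 <= 0)
    stop("theta_h1: sigma2 must be a positive scalar")
  structure(list(rho_tilde = rho_tilde, tau1 = as.numeric(tau1),
                 sigma2 = as.numeric(sigma2), beta = as.numeric(beta)),
            class = "bkat_theta_h1")
}

#' Parameters of the null model (tau1 = 0)
#'
#' @param sigma2 positive residual variance.
#' @param beta covariate coefficient vector.
#' @return An object of class \code{bkat_theta_h0}.
#' @export
theta_h0 <- function(sigma2, beta) {
  if (length(sigma2) != 1L || sigma2 <= 0)
    stop("theta_h0: sigma2 must be a positive scalar")
  structure(list(sigma2 = as.numeric(sigma2), beta = as.numeric(beta)),
            class = "bkat_theta_h0")
}
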