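#' Candidate kernels and composite kernel construction
#'
#' A group-level test compares individuals through an n x n similarity
#' (kernel) matrix computed from the feature matrix Z.  Candidate kernels
#' capture different functional forms of the feature-phenotype relationship:
#' Linear (additive), Quadratic (pairwise interactions), Gaussian (smooth
#' nonlinear) and IBS (allele-sharing for 0/1/2 genotypes).  Candidates are
#' trace-normalized so their scales are comparable before they are combined
#' into the composite kernel \eqn{K_c = \sum_i \rho_i K_i}.
#'
#' @name kernels
NULL

new_kernel <- function(values, name, normalized = FALSE) {
  dimnames(values) <- NULL
  structure(list(values = values, name = name, normalized = normalized),
            class = "bkat_kernel")
}

#' @export
print.bkat_kernel <- function(x, ...) {
  cat("bkat_kernel '", x$name, "': ", nrow(x$values), " x ", ncol(x$values),
      if (x$normalized) ", normalized" else "", "\n", sep = "")
  invisible(x)
}

check_Z <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L || ncol(Z) < 1L)
    stop("kernel: feature matrix Z must be non-empty")
  if (anyNA(Z)) stop("kernel: Z contains missing values")
  storage.mode(Z) <- "double"
  Z
}

#' Linear kernel K(i,j) = z_i' z_j
#' @param Z numeric n x p feature matrix.
#' @return A \code{bkat_kernel} (un-normalized Gram matrix).
#' @export
linear_kernel <- function(Z) {
  Z <- check_Z(Z)
  new_kernel(tcrossprod(Z), "Linear")
}

#' Quadratic kernel K(i,j) = (1 + z_i' z_j)^2
#' @inheritParams linear_kernel
#' @return A \code{bkat_kernel}.
#' @export
quadratic_kernel <- function(Z) {
  Z <- check_Z(Z)
  new_kernel((1 + tcrossprod(Z))^2, "Quadratic")
}

#' Gaussian kernel K(i,j) = exp(-||z_i - z_j||^2 / bandwidth)
#'
#' @inheritParams linear_kernel
#' @param bandwidth positive length-scale; defaults to the feature count p.
#'   Set \code{bandwidth = "median"} for the median heuristic (median of the
#'   nonzero squared pairwise distances).
#' @return A \code{bkat_kernel} with unit diagonal.
#' @export
gaussian_kernel <- function(Z, bandwidth = ncol(as.matrix(Z))) {
  Z <- check_Z(Z)
  d2 <- as.matrix(stats::dist(Z))^2
  if (identical(bandwidth, "median")) {
    pos <- d2[upper.tri(d2)]
    pos <- pos[pos > 0]
    bandwidth <- if (length(pos)) stats::median(pos) else 1
  }
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("gaussian_kernel: bandwidth must be a positive scalar")
  K <- exp(-d2 / bandwidth)
  diag(K) <- 1
  new_kernel(K, "Gaussian")
}

#' IBS (identity-by-state) kernel for 0/1/2 genotypes
#'
#' K(i,j) = sum_l (2 - |z_il - z_jl|) / (2 p): the average number of shared
#' alleles per locus, in [0, 1] with unit diagonal.
#'
#' @param Z integer n x p genotype matrix with entries in \{0, 1, 2\}.
#' @return A \code{bkat_kernel}.
#' @export
ibs_kernel <- function(Z) {
  Z <- check_Z(Z)
  bad <- which(!(Z %in% c(0, 1, 2)))
  if (length(bad)) {
    j <- ceiling(bad[1] / nrow(Z))
    stop("ibs_kernel: non-genotype value in feature column ", j,
         " (entries must be 0, 1 or 2)")
  }
  p <- ncol(Z)
  # sum_l |z_il - z_jl| decomposed by genotype value to stay O(n^2 p) in BLAS:
  # |a-b| = a + b - 2*min(a,b); min(a,b) = 1[a>=1]1[b>=1] + 1[a==2]1[b==2]
  ge1 <- (Z >= 1) * 1
  eq2 <- (Z == 2) * 1
  rs <- rowSums(Z)
  absdiff <- outer(rs, rs, "+") - 2 * (tcrossprod(ge1) + tcrossprod(eq2))
  K <- (2 * p - absdiff) / (2 * p)
  diag(K) <- 1
  new_kernel(K, "IBS")
}

#' Trace-normalize a kernel matrix to trace n
#'
#' Rescales K to n * K / trace(K) so that all candidates live on a common
#' scale before composition; idempotent and invariant to positive rescaling
#' of the input.
#'
#' @param K a \code{bkat_kernel} or plain symmetric matrix.
#' @return A normalized \code{bkat_kernel}.
#' @export
normalize_kernel <- function(K) {
  if (is.matrix(K)) K <- new_kernel(K, "kernel")
  tr <- sum(diag(K$values))
  if (tr <= 0) stop("normalize_kernel: degenerate kernel with trace <= 0")
  new_kernel(nrow(K$values) * K$values / tr, K$name, normalized = TRUE)
}

#' Bundle normalized candidate kernels
#'
#' @param ... \code{bkat_kernel} objects (or a single list of them).  Each is
#'   trace-normalized if not already.
#' @return An object of class \code{bkat_kernel_set}.
#' @export
kernel_set <- function(...) {
  ks <- list(...)
  if (length(ks) == 1L && !inherits(ks[[1]], "bkat_kernel")) ks <- ks[[1]]
  if (!length(ks)) stop("kernel_set: need at least one kernel")
  ks <- lapply(ks, function(k) {
    if (!inherits(k, "bkat_kernel")) stop("kernel_set: not a bkat_kernel")
    if (k$normalized) k else normalize_kernel(k)
  })
  nms <- vapply(ks, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("kernel_set: kernel names must be unique")
  ns <- vapply(ks, function(k) nrow(k$values), integer(1))
  if (length(unique(ns)) != 1L)
    stop("kernel_set: kernels have differing dimensions")
  names(ks) <- nms
  structure(list(kernels = ks, names = nms, n = ns[1]),
            class = "bkat_kernel_set")
}

#' @export
print.bkat_kernel_set <- function(x, ...) {
  cat("bkat_kernel_set: ", length(x$kernels), " kernels (",
      paste(x$names, collapse = ", "), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
length.bkat_kernel_set <- function(x) length(x$kernels)

#' Default candidate kernel set for a feature matrix
#'
#' Genotype input uses \{IBS, Quadratic, Gaussian\}; continuous input uses
#' \{Linear, Quadratic, Gaussian\}.  Continuous features are standardized
#' (per-feature z-score) before the Quadratic and Gaussian kernels by
#' default, so that unbounded feature scales do not dominate the polynomial
#' kernel; genotypes are used as-is.
#'
#' @param Z feature matrix.
#' @param type \code{"continuous"} or \code{"genotype"}; default guesses
#'   genotype when all entries are in \{0, 1, 2\}.
#' @param standardize standardize features before Quadratic/Gaussian kernels
#'   (default: TRUE for continuous, FALSE for genotype).
#' @param names optional subset of kernel names to build.
#' @return A \code{bkat_kernel_set} of normalized kernels.
#' @export
default_kernels <- function(Z, type = NULL, standardize = NULL, names = NULL) {
  Z <- check_Z(Z)
  if (is.null(type))
    type <- if (all(Z %in% c(0, 1, 2))) "genotype" else "continuous"
  type <- match.arg(type, c("continuous", "genotype"))
  if (is.null(standardize)) standardize <- type == "continuous"
  if (is.null(names))
    names <- if (type == "genotype") c("IBS", "Quadratic", "Gaussian")
             else c("Linear", "Quadratic", "Gaussian")
  Zs <- Z
  if (standardize) {
    sds <- apply(Z, 2, stats::sd)
    sds[sds == 0] <- 1
    Zs <- scale(Z, center = TRUE, scale = sds)
  }
  build <- function(nm) switch(nm,
    Linear    = linear_kernel(Z),
    Quadratic = quadratic_kernel(Zs),
    Gaussian  = gaussian_kernel(Zs),
    IBS       = ibs_kernel(Z),
    stop("default_kernels: unknown kernel name '", nm, "'"))
  kernel_set(lapply(names, build))
}

#' Composite kernel K_c = sum_i rho_i K_i
#'
#' @param kernels a \code{bkat_kernel_set} of m normalized kernels.
#' @param rho simplex weight vector of length m (entries >= 0, summing to 1),
#'   aligned to the kernel order.
#' @return A \code{bkat_kernel} (normalized: trace n by convexity).
#' @export
composite_kernel <- function(kernels, rho) {
  rho <- as.numeric(rho)
  if (length(rho) != length(kernels$kernels))
    stop("composite_kernel: length(rho) != number of kernels")
  if (any(rho < -1e-12) || abs(sum(rho) - 1) > 1e-8)
    stop("composite_kernel: rho must lie on the simplex")
  K <- composite_kernel_values(kernels, rho)
  new_kernel(K, paste0("Composite(", paste(kernels$names, collapse = ","), ")"),
             normalized = TRUE)
}

# fast internal path: plain matrix, no validation
composite_kernel_values <- function(kernels, rho) {
  ks <- kernels$kernels
  K <- rho[1] * ks[[1]]$values
  if (length(ks) > 1L)
    for (i in 2:length(ks)) K <- K + rho[i] * ks[[i]]$values
  K
}
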