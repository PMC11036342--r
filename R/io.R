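#' File readers and writers
#'
#' Delimited-text ingestion for genotype/feature matrices (plain TSV or the
#' PLINK .raw recoded-additive dialect), covariate and phenotype tables and
#' group definitions, plus the result-table writer.
#'
#' @name io
NULL

#' Read a genotype / feature matrix
#'
#' \code{format = "tsv"}: tab-separated, header \code{sample_id} followed by
#' one column per feature.  \code{format = "raw"}: the PLINK recoded
#' (\code{--recode A}) dialect — whitespace-delimited with header columns
#' FID IID PAT MAT SEX PHENOTYPE followed by SNP_ALLELE columns holding
#' 0/1/2 or NA.  Missing genotypes are imputed with the per-SNP mean of the
#' observed genotypes (rounded to the nearest integer under
#' \code{impute = "round"}, as required by the IBS kernel); the imputation
#' count is reported via a message.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"raw"}.
#' @param impute \code{"mean"} or \code{"round"}.
#' @return A list: \code{sample_ids}, \code{feature_ids}, \code{Z},
#'   \code{n_imputed}.
#' @export
read_genotypes <- function(path, format = c("tsv", "raw"),
                           impute = c("mean", "round")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("read_genotypes: file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "sample_id")
      stop("read_genotypes: malformed header (line 1): first column must ",
           "be 'sample_id'")
    ids <- as.character(df[[1]])
    Z <- as.matrix(df[, -1, drop = FALSE])
    feature_ids <- colnames(Z)
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                            na.strings = c("NA", "-9"))
    req <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 7L || !identical(names(df)[1:6], req))
      stop("read_genotypes: malformed .raw header (line 1): expected ",
           paste(req, collapse = " "), " then SNP columns")
    ids <- as.character(df$IID)
    Z <- as.matrix(df[, -(1:6), drop = FALSE])
    feature_ids <- colnames(Z)
  }
  if (anyDuplicated(ids))
    stop("read_genotypes: duplicate sample_id: ",
         ids[duplicated(ids)][1])
  dimnames(Z) <- NULL
  storage.mode(Z) <- "double"
  obs <- Z[!is.na(Z)]
  if (length(obs) && !all(obs %in% c(0, 1, 2)) && format == "raw")
    stop("read_genotypes: non-{0,1,2,NA} genotype in column ",
         feature_ids[which(!apply(Z, 2, function(col)
           all(is.na(col) | col %in% c(0, 1, 2))))[1]])
  n_imputed <- sum(is.na(Z))
  if (n_imputed) {
    for (j in which(colSums(is.na(Z)) > 0)) {
      mu <- mean(Z[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      if (impute == "round") mu <- round(mu)
      Z[is.na(Z[, j]), j] <- mu
    }
    message("read_genotypes: imputed ", n_imputed, " missing genotypes (",
            impute, ")")
  }
  list(sample_ids = ids, feature_ids = feature_ids, Z = Z,
       n_imputed = n_imputed)
}

#' Read a covariate or phenotype table
#'
#' Delimited text with a header containing a \code{sample_id} column; all
#' other columns must be numeric.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return A data.frame with a character \code{sample_id} column.
#' @export
read_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("read_table: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("read_table: no 'sample_id' column in ", path)
  df$sample_id <- as.character(df$sample_id)
  for (nm in setdiff(names(df), "sample_id")) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn)))
        stop("read_table: non-numeric values in column '", nm, "'")
      df[[nm]] <- vn
    }
  }
  df
}

#' Assemble aligned model data from ingested fragments
#'
#' Joins covariates and phenotype to the genotype sample order by
#' \code{sample_id}, appends an intercept column unless disabled, drops
#' samples with missing phenotype (with a warning) and errors on missing
#' covariate cells.
#'
#' @param genotypes a \code{\link{read_genotypes}} result.
#' @param covariates a covariate data.frame from \code{\link{read_table}}
#'   (or NULL for intercept-only).
#' @param phenotype a phenotype data.frame from \code{\link{read_table}}
#'   with exactly one value column.
#' @param add_intercept prepend a constant-1 column to X (default TRUE).
#' @return A \code{\link{model_data}}.
#' @export
assemble_model_data <- function(genotypes, covariates, phenotype,
                                add_intercept = TRUE) {
  ids <- genotypes$sample_ids
  ph_col <- setdiff(names(phenotype), "sample_id")
  if (length(ph_col) != 1L)
    stop("assemble_model_data: phenotype table must have exactly one value ",
         "column")
  mi <- match(ids, phenotype$sample_id)
  if (anyNA(mi)) {
    missing_ids <- ids[is.na(mi)][seq_len(min(10, sum(is.na(mi))))]
    stop("assemble_model_data: samples without phenotype: ",
         paste(missing_ids, collapse = ", "))
  }
  y <- phenotype[[ph_col]][mi]
  keep <- !is.na(y)
  if (!all(keep))
    warning("assemble_model_data: dropped ", sum(!keep),
            " samples with missing phenotype")
  ids <- ids[keep]
  y <- y[keep]
  Z <- genotypes$Z[keep, , drop = FALSE]

  if (!is.null(covariates)) {
    mc <- match(ids, covariates$sample_id)
    if (anyNA(mc)) {
      missing_ids <- ids[is.na(mc)][seq_len(min(10, sum(is.na(mc))))]
      stop("assemble_model_data: samples without covariates: ",
           paste(missing_ids, collapse = ", "))
    }
    Xd <- covariates[mc, setdiff(names(covariates), "sample_id"),
                     drop = FALSE]
    if (anyNA(Xd))
      stop("assemble_model_data: missing covariate cells (covariates must ",
           "be complete)")
    X <- as.matrix(Xd)
    dimnames(X) <- list(NULL, colnames(Xd))
  } else {
    X <- matrix(numeric(0), nrow = length(ids), ncol = 0)
  }
  if (add_intercept)
    X <- cbind(`(Intercept)` = 1, X)
  if (!ncol(X))
    stop("assemble_model_data: X has no columns; enable add_intercept or ",
         "provide covariates")
  model_data(y, X, Z, sample_ids = ids,
             feature_ids = genotypes$feature_ids)
}

#' Read group definitions
#'
#' Accepts either a two-column delimited file (group_id, feature_id; header
#' optional, detected from the first line) or a JSON object mapping group
#' ids to arrays of feature ids.
#'
#' @param path file path (.json files are parsed as JSON).
#' @param feature_ids optional universe of known features: group members
#'   absent from it are dropped with a warning and groups left empty are
#'   skipped.
#' @return Named list of character vectors (one per group).
#' @export
read_groups <- function(path, feature_ids = NULL) {
  if (!file.exists(path)) stop("read_groups: file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    groups <- lapply(g, as.character)
  } else {
    first <- readLines(path, n = 1L)
    has_header <- grepl("group", first, ignore.case = TRUE)
    df <- if (has_header)
      utils::read.table(path, header = TRUE, sep = "",
                        stringsAsFactors = FALSE)
    else
      utils::read.table(path, header = FALSE, sep = "",
                        col.names = c("group_id", "feature_id"),
                        stringsAsFactors = FALSE)
    names(df)[1:2] <- c("group_id", "feature_id")
    groups <- split(as.character(df$feature_id), df$group_id)
  }
  if (!length(groups)) stop("read_groups: no groups in ", path)
  groups <- lapply(groups, unique)
  if (!is.null(feature_ids)) {
    for (g in names(groups)) {
      unknown <- setdiff(groups[[g]], feature_ids)
      if (length(unknown)) {
        warning("read_groups: group '", g, "' has ", length(unknown),
                " unknown feature(s); dropped")
        groups[[g]] <- setdiff(groups[[g]], unknown)
      }
    }
    empty <- names(groups)[lengths(groups) == 0L]
    if (length(empty)) {
      warning("read_groups: skipping empty group(s): ",
              paste(empty, collapse = ", "))
      groups <- groups[lengths(groups) > 0L]
    }
  }
  groups
}

#' Test every group for association
#'
#' Runs the chosen engine once per group (on the feature columns of that
#' group), assembles the result table, applies the posterior threshold and
#' the Bayesian FDR adjustment.  Per-group failures are logged and marked,
#' not fatal.
#'
#' @param data a \code{\link{model_data}} covering all features.
#' @param groups named list of feature-id vectors.
#' @param engine \code{"map"} or \code{"mcmc"}.
#' @param kernels optional kernel names (default by feature type).
#' @param priors a \code{\link{prior_spec}}.
#' @param threshold posterior-probability selection threshold.
#' @param fdr_q Bayesian FDR target.
#' @param seed integer seed.
#' @param engine_config optional engine configuration.
#' @param threads number of parallel workers across groups.
#' @return A group result data.frame (see \code{\link{group_result_table}})
#'   with \code{selected} and \code{efdr} columns.
#' @export
bkat_test <- function(data, groups, engine = c("map", "mcmc"),
                      kernels = NULL, priors = prior_spec(),
                      threshold = 0.7, fdr_q = 0.05, seed = 1L,
                      engine_config = NULL, threads = 1L) {
  engine <- match.arg(engine)
  run_group <- function(g) {
    fid <- intersect(groups[[g]], data$feature_ids)
    Zg <- data$Z[, match(fid, data$feature_ids), drop = FALSE]
    dg <- model_data(data$y, data$X, Zg, data$sample_ids, fid)
    ker <- default_kernels(Zg, names = kernels)
    tryCatch({
      if (engine == "map") {
        ec <- engine_config %||% map_config()
        ec$seed <- seed
        bkat_map(dg, ker, priors, ec)
      } else {
        ec <- engine_config %||% mcmc_config()
        ec$seed <- seed
        bkat_mcmc(dg, ker, priors, ec)
      }
    }, error = function(e) e)
  }
  gnames <- names(groups)
  results <- if (threads > 1L)
    parallel::mclapply(gnames, run_group, mc.cores = threads)
  else lapply(gnames, run_group)
  names(results) <- gnames
  failed <- vapply(results, inherits, logical(1), "error")
  for (g in gnames[failed])
    warning("bkat_test: group '", g, "' failed: ",
            conditionMessage(results[[g]]))
  ok <- results[!failed]
  if (!length(ok)) stop("bkat_test: all groups failed")
  tab <- group_result_table(ok, n_features = vapply(
    gnames[!failed], function(g)
      length(intersect(groups[[g]], data$feature_ids)), integer(1)))
  tab <- select_groups(tab, threshold)
  tab <- multiplicity_adjust(tab, q = fdr_q)
  tab
}

#' Write a group result table as TSV
#'
#' Fixed column order: group_id, n_features, log_bf10, posterior_h1, the
#' rho_* weight columns, tau1_hat, sigma2_hat, engine, psrf_max, converged,
#' selected, efdr.
#'
#' @param table result data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_group_results <- function(table, path) {
  rho_cols <- grep("^rho_", names(table), value = TRUE)
  order_cols <- c("group_id", "n_features", "log_bf10", "posterior_h1",
                  rho_cols, "tau1_hat", "sigma2_hat", "engine", "psrf_max",
                  "converged", "selected", "efdr")
  order_cols <- intersect(order_cols, names(table))
  utils::write.table(table[, order_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
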