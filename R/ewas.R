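## Site-wise EWAS pipeline: dataset ingestion, per-site model fitting
## with Wald tests, and BH/BY false discovery rate control.

#' Construct a methylation dataset
#'
#' Bundles a sites-by-samples beta-value matrix with a per-sample
#' covariate table. Sample identifiers of the matrix columns and the
#' covariate rows must match as sets; samples present in only one of the
#' two are dropped with a warning when they are fewer than
#' \code{max_unmatched_frac} of the total, and raise an error otherwise.
#'
#' @param betas numeric matrix, rows = CpG sites (rownames = site ids),
#'   columns = samples (colnames = sample ids), values in \[0, 1\].
#' @param covariates data.frame with rownames (or a \code{sample_id}
#'   column) identifying samples.
#' @param max_unmatched_frac tolerated fraction of unmatched samples
#'   (default 0.1).
#' @param max_missing_frac per-site missingness threshold; sites above it
#'   are rejected (default 0.05, a standard low-confidence filter level).
#' @return Object of class \code{"methylation_dataset"} with aligned
#'   \code{betas} and \code{covariates}.
#' @export
methylation_dataset <- function(betas, covariates,
                                max_unmatched_frac = 0.1,
                                max_missing_frac = 0.05) {
  betas <- as.matrix(betas)
  if (is.null(rownames(betas)))
    rownames(betas) <- paste0("site", seq_len(nrow(betas)))
  if (is.null(colnames(betas))) stop("beta matrix must have sample ids")
  if ("sample_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  if (is.null(rownames(covariates)))
    stop("covariate table must carry sample ids")
  common <- intersect(colnames(betas), rownames(covariates))
  n_all <- length(union(colnames(betas), rownames(covariates)))
  n_drop <- n_all - length(common)
  if (length(common) < 2) stop("no overlapping samples")
  if (n_drop / n_all > max_unmatched_frac)
    stop(sprintf("%d of %d sample ids unmatched between matrix and covariates",
                 n_drop, n_all))
  if (n_drop > 0)
    warning(sprintf("dropping %d unmatched sample(s)", n_drop))
  betas <- betas[, common, drop = FALSE]
  covariates <- covariates[common, , drop = FALSE]
  miss <- rowMeans(is.na(betas))
  if (any(miss > max_missing_frac))
    stop(sprintf("%d site(s) exceed %.0f%% missing beta values",
                 sum(miss > max_missing_frac), 100 * max_missing_frac))
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values outside [0, 1]")
  structure(list(betas = betas, covariates = covariates),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation dataset: %d sites x %d samples, %d covariate(s)\n",
              nrow(x$betas), ncol(x$betas), ncol(x$covariates)))
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$betas)

#' Read a methylation dataset from delimited text files
#'
#' The beta matrix file has sites in rows (first column = site id,
#' header = sample ids); the covariate file has one sample per row
#' (first column or a \code{sample_id} column = sample id). When raw
#' intensity matrices are supplied instead of beta values
#' (\code{m_path}/\code{u_path}), beta values are computed as
#' \eqn{b = M/(M+U+a)} with the stabilizing offset \code{offset}
#' (default 100, the customary value).
#'
#' @param beta_path path to the beta matrix (TSV/CSV); ignored when
#'   \code{m_path} and \code{u_path} are given.
#' @param covariate_path path to the covariate table.
#' @param m_path,u_path optional paths to methylated/unmethylated
#'   intensity matrices of identical layout.
#' @param offset stabilizing offset a added to M + U (default 100).
#' @param max_unmatched_frac see [methylation_dataset()].
#' @return A \code{"methylation_dataset"}.
#' @export
read_dataset <- function(beta_path = NULL, covariate_path,
                         m_path = NULL, u_path = NULL, offset = 100,
                         max_unmatched_frac = 0.1) {
  read_matrix <- function(path) {
    dt <- data.table::fread(path, header = TRUE)
    ids <- as.character(dt[[1]])
    mat <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(mat))
      stop("non-numeric cells in ", path)
    rownames(mat) <- ids
    mat
  }
  if (!is.null(m_path) || !is.null(u_path)) {
    if (is.null(m_path) || is.null(u_path))
      stop("both 'm_path' and 'u_path' are required for intensity input")
    M <- read_matrix(m_path)
    U <- read_matrix(u_path)
    if (!identical(dim(M), dim(U)) || !identical(dimnames(M), dimnames(U)))
      stop("M and U matrices have different layouts")
    if (offset < 0) stop("'offset' must be >= 0")
    betas <- M / (M + U + offset)
  } else {
    if (is.null(beta_path)) stop("either beta or intensity paths required")
    betas <- read_matrix(beta_path)
  }
  cov_dt <- data.table::fread(covariate_path, header = TRUE)
  covariates <- as.data.frame(cov_dt)
  idcol <- if ("sample_id" %in% names(covariates)) "sample_id" else
    names(covariates)[1]
  rownames(covariates) <- as.character(covariates[[idcol]])
  covariates[[idcol]] <- NULL
  methylation_dataset(betas, covariates,
                      max_unmatched_frac = max_unmatched_frac)
}

#' Adjust p-values for multiple testing (BH / BY)
#'
#' Step-up false discovery rate adjustment: Benjamini-Hochberg
#' (\code{"BH"}) or Benjamini-Yekutieli (\code{"BY"}, the BH adjustment
#' inflated by the harmonic sum \eqn{\sum_{i=1}^m 1/i}, valid under
#' arbitrary dependence). Thin wrapper over [stats::p.adjust()].
#'
#' @param p p-values in \[0, 1\].
#' @param method \code{"BH"} or \code{"BY"}.
#' @return Adjusted values, same length as \code{p}.
#' @export
adjust_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = method)
}

#' Site-wise regression across a methylation dataset
#'
#' Fits the chosen model independently at every CpG site and reports the
#' Wald test for each requested coefficient, with BH- and BY-adjusted
#' p-values computed per coefficient across sites. Sites are independent:
#' the result is invariant to site order, and per-site failures are
#' flagged rather than fatal.
#'
#' @param dataset a [methylation_dataset()].
#' @param model \code{"rcg"}, \code{"betareg"} or \code{"mvalue"}.
#' @param covariates character vector of covariate columns to adjust for
#'   (default: all columns).
#' @param test coefficients to report (default: all covariates).
#' @param level nominal size for the per-site tests.
#' @return data.frame of class \code{"ewas_result"} with columns
#'   \code{site}, \code{coef}, \code{estimate}, \code{se}, \code{z},
#'   \code{p}, \code{q_bh}, \code{q_by}, \code{model}, \code{converged}.
#' @export
run_sitewise <- function(dataset, model = c("rcg", "betareg", "mvalue"),
                         covariates = NULL, test = NULL, level = 0.05) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  model <- match.arg(model)
  if (is.null(covariates)) covariates <- names(dataset$covariates)
  X <- build_design(dataset$covariates, select = covariates)
  if (is.null(test)) test <- setdiff(colnames(X), "(Intercept)")
  bad <- setdiff(test, colnames(X))
  if (length(bad)) stop("unknown test coefficient(s): ",
                        paste(bad, collapse = ", "))
  fitter <- switch(model, rcg = fit_rcg, betareg = fit_betareg,
                   mvalue = fit_mvalue)
  sites <- rownames(dataset$betas)
  rows <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    b <- clamp_beta(as.numeric(dataset$betas[i, ]), quiet = TRUE)
    fit <- try(fitter(b, X), silent = TRUE)
    failed <- inherits(fit, "try-error") ||
      (!is.null(fit$converged) && !fit$converged)
    if (failed) {
      rows[[i]] <- data.frame(site = sites[i], coef = test,
                              estimate = NA_real_, se = NA_real_,
                              z = NA_real_, p = NA_real_,
                              model = model, converged = FALSE)
    } else {
      wt <- lapply(test, function(k) wald_test(fit, k, level = level))
      rows[[i]] <- data.frame(
        site = sites[i], coef = test,
        estimate = vapply(wt, `[[`, 0, "estimate"),
        se = vapply(wt, `[[`, 0, "se"),
        z = vapply(wt, `[[`, 0, "z"),
        p = vapply(wt, `[[`, 0, "p"),
        model = model, converged = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_bh <- NA_real_
  out$q_by <- NA_real_
  for (k in test) {
    sel <- out$coef == k & !is.na(out$p)
    out$q_bh[sel] <- adjust_fdr(out$p[sel], "BH")
    out$q_by[sel] <- adjust_fdr(out$p[sel], "BY")
  }
  out <- out[, c("site", "coef", "estimate", "se", "z", "p",
                 "q_bh", "q_by", "model", "converged")]
  rownames(out) <- NULL
  class(out) <- c("ewas_result", class(out))
  out
}

#' Write an EWAS result table as TSV
#'
#' @param result a [run_sitewise()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_ewas_results <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}
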