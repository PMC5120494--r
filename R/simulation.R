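## Declarative simulation harness: type-I error / power studies under the
## direct ratio generator and the Gumbel-copula generator, a multi-site
## extension over a table of per-site parameters, and the train/test
## log-score comparison of the three model families.

## Reference effect sizes: maximum-likelihood estimates at a single CpG
## site of a population cohort (intercept, gender, age, bmi, smoke,
## depression), shape alpha and intensity correlation rho.
.CG_REF_GAMMA <- c(-1.099, 0.096, -0.007, -0.004, 0.003, 0.001)
.CG_REF_ALPHA <- 5.84
.CG_REF_RHO <- 0.93
## Log-rate coefficient vectors of the copula generator (same covariate
## order); gender entry of zeta_m is varied to set the gender effect.
.CG_REF_ZETA_M <- c(-6.2777, NA, 0.0003, -0.0001, -0.0199, 0.0010)
.CG_REF_ZETA_U <- c(-5.6424, -0.0731, 0.0088, 0.0016, -0.0073, -0.0014)
.CG_REF_ALPHA_M <- 20.2
.CG_REF_ALPHA_U <- 12.760

#' Reference single-site parameter set
#'
#' The RCG estimates (coefficients for intercept, gender, age, BMI,
#' smoking, depression; shape; correlation) at the reference CpG site
#' cg00786084 used throughout the power studies, and the marginal
#' log-rate coefficients of the copula generator.
#'
#' @return Named list with \code{gamma}, \code{alpha}, \code{rho},
#'   \code{zeta_m}, \code{zeta_u}, \code{alpha_m}, \code{alpha_u}.
#' @export
reference_site_params <- function() {
  list(gamma = setNames(.CG_REF_GAMMA,
                        c("(Intercept)", "gender", "age", "bmi",
                          "smoke", "depression")),
       alpha = .CG_REF_ALPHA, rho = .CG_REF_RHO,
       zeta_m = .CG_REF_ZETA_M, zeta_u = .CG_REF_ZETA_U,
       alpha_m = .CG_REF_ALPHA_M, alpha_u = .CG_REF_ALPHA_U)
}

#' Declare a power / type-I-error simulation design
#'
#' @param generator \code{"rcg_ratio"} (beta values straight from the
#'   ratio density) or \code{"gumbel_copula"} (intensities from the
#'   Gumbel-copula construction, then b = M/(M+U)).
#' @param n_subjects subjects per replicate (default 1118, the cohort
#'   size the reference estimates come from).
#' @param n_replicates Monte-Carlo replicates per effect value.
#' @param effects numeric grid of values for the tested (gender)
#'   coefficient; 0 is the null.
#' @param rho intensity correlation (ratio generator) or target Pearson
#'   correlation for copula calibration.
#' @param alpha gamma shape of the ratio generator.
#' @param gamma_fixed full coefficient vector; the gender entry (index 2)
#'   is overwritten by each effect value.
#' @param level nominal test size.
#' @param models which model families to fit each replicate.
#' @param seed integer seed governing the whole study (covariate draw and
#'   all replicates).
#' @return Object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(generator = c("rcg_ratio", "gumbel_copula"),
                              n_subjects = 1118L, n_replicates = 1000L,
                              effects = 0, rho = .CG_REF_RHO,
                              alpha = .CG_REF_ALPHA,
                              gamma_fixed = .CG_REF_GAMMA,
                              level = 0.05,
                              models = c("rcg", "betareg", "mvalue"),
                              seed = 1L) {
  generator <- match.arg(generator)
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(n_replicates >= 1, level > 0, level < 1)
  structure(list(generator = generator, n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates),
                 effects = as.numeric(effects), rho = rho, alpha = alpha,
                 gamma_fixed = as.numeric(gamma_fixed), level = level,
                 models = models, seed = as.integer(seed)),
            class = "simulation_design")
}

## one replicate: fit requested models, return named logical rejections
## and a convergence flag for the RCG fit
.fit_and_test <- function(b, X, models, level, test_coef = "gender") {
  out <- setNames(rep(NA, length(models)), models)
  conv <- TRUE
  for (mdl in models) {
    fit <- switch(mdl,
      rcg = try(fit_rcg(b, X), silent = TRUE),
      betareg = try(fit_betareg(b, X), silent = TRUE),
      mvalue = try(fit_mvalue(b, X), silent = TRUE))
    if (inherits(fit, "try-error") ||
        (!is.null(fit$converged) && !fit$converged)) {
      if (mdl == "rcg") conv <- FALSE
      out[mdl] <- NA
    } else {
      out[mdl] <- wald_test(fit, test_coef, level = level)$reject
    }
  }
  list(reject = out, rcg_converged = conv)
}

#' Run a power / type-I-error study
#'
#' For each effect value: the gender coefficient is set to that value, a
#' fixed covariate matrix (drawn once per study from
#' [hnr_covariate_spec()], mimicking conditioning on the real cohort
#' covariates) is reused across replicates, beta values are generated
#' from the requested generator, each requested model is fitted, and the
#' level-\code{level} Wald test for the gender coefficient is tabulated.
#' A replicate whose RCG fit fails to converge is re-drawn once and, if
#' it fails again, counted as a non-rejection.
#'
#' @param design a [simulation_design()] object.
#' @return Object of class \code{"simulation_result"}: a data.frame with
#'   columns \code{generator}, \code{rho}, \code{effect}, \code{model},
#'   \code{rejections}, \code{replicates}, \code{rejection_rate},
#'   \code{mc_se}, \code{n_nonconverged}.
#' @export
run_power_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  covs <- sample_covariates(design$n_subjects)
  X <- build_design(covs)
  if (ncol(X) != length(design$gamma_fixed))
    stop("gamma_fixed length does not match the covariate design")

  copula <- NULL
  if (design$generator == "gumbel_copula") {
    rho_tilde <- if (design$rho == 0) 1 else
      calibrate_copula(design$rho, .CG_REF_ALPHA_M, .CG_REF_ALPHA_U,
                       seed = design$seed)
    copula <- list(rho_tilde = rho_tilde)
  }

  rows <- list()
  for (effect in design$effects) {
    gamma_true <- design$gamma_fixed
    gamma_true[2] <- effect
    theta <- exp(drop(X %*% gamma_true))
    if (!is.null(copula)) {
      zeta_u <- .CG_REF_ZETA_U
      ## gamma = zeta_m - zeta_u componentwise; gender entry of zeta_m
      ## is set so that the implied gender effect equals `effect`
      zeta_m <- zeta_u + gamma_true
      cd <- copula_design(copula$rho_tilde, .CG_REF_ALPHA_M,
                          .CG_REF_ALPHA_U, zeta_m, zeta_u,
                          target_rho = design$rho)
    }
    draw_b <- function() {
      if (design$generator == "rcg_ratio") {
        sample_rcg_beta(design$n_subjects, design$alpha, design$rho, theta)
      } else {
        mu_pair <- sample_gumbel_pair(design$n_subjects, cd, X)
        mu_pair[, 1] / (mu_pair[, 1] + mu_pair[, 2])
      }
    }
    rej <- matrix(0L, nrow = design$n_replicates,
                  ncol = length(design$models),
                  dimnames = list(NULL, design$models))
    n_nc <- 0L
    for (r in seq_len(design$n_replicates)) {
      b <- draw_b()
      res <- .fit_and_test(b, X, design$models, design$level)
      if (!res$rcg_converged) {        # re-draw once, then give up
        b <- draw_b()
        res <- .fit_and_test(b, X, design$models, design$level)
        if (!res$rcg_converged) n_nc <- n_nc + 1L
      }
      rej[r, ] <- ifelse(is.na(res$reject), 0L, as.integer(res$reject))
    }
    for (mdl in design$models) {
      k <- sum(rej[, mdl])
      R <- design$n_replicates
      phat <- k / R
      rows[[length(rows) + 1L]] <- data.frame(
        generator = design$generator, rho = design$rho, effect = effect,
        model = mdl, rejections = k, replicates = R,
        rejection_rate = phat, mc_se = sqrt(phat * (1 - phat) / R),
        n_nonconverged = n_nc)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("simulation_result", class(out))
  out
}

#' Synthetic per-site RCG parameter table
#'
#' Generates \code{n_sites} plausible combinations of (alpha, rho,
#' gamma): correlations match the cohort-wide distribution of
#' intensity correlations (mean 0.45, sd 0.14, truncated to \[0, 0.99\]),
#' shapes are log-normal around the reference site's estimate, intercepts
#' spread over typical methylation levels, and gender effects are mostly
#' near zero with a minority of moderate effects. This synthetic table
#' stands in for per-site estimates from a real cohort, which are not
#' distributable.
#'
#' @param n_sites number of sites.
#' @param seed integer seed.
#' @return data.frame with columns \code{site}, \code{alpha}, \code{rho},
#'   \code{gamma0}, \code{gamma_gender}, \code{gamma_age},
#'   \code{gamma_bmi}, \code{gamma_smoke}, \code{gamma_depression}.
#' @export
synthetic_site_params <- function(n_sites = 1000L, seed = 20161122L) {
  .with_seed(seed, {
    rho <- pmin(pmax(rnorm(n_sites, 0.45, 0.14), 0), 0.99)
    alpha <- exp(rnorm(n_sites, base::log(5.84), 0.5))
    gamma0 <- rnorm(n_sites, -0.5, 1.2)
    big <- rbinom(n_sites, 1, 0.3) == 1
    gg <- ifelse(big, rnorm(n_sites, 0, 0.25), rnorm(n_sites, 0, 0.01))
    data.frame(site = sprintf("syn%05d", seq_len(n_sites)),
               alpha = alpha, rho = rho, gamma0 = gamma0,
               gamma_gender = gg,
               gamma_age = rnorm(n_sites, 0, 0.004),
               gamma_bmi = rnorm(n_sites, 0, 0.004),
               gamma_smoke = rnorm(n_sites, 0, 0.01),
               gamma_depression = rnorm(n_sites, 0, 0.002))
  })
}

#' Multi-site power study over a table of per-site parameters
#'
#' For each site in the table, estimates the rejection rate of the Wald
#' test on the gender coefficient by simulating \code{n_replicates}
#' datasets of \code{n_subjects} beta values from the ratio density at
#' that site's parameters (one shared covariate matrix across sites and
#' replicates). Results are grouped by deciles of the absolute gender
#' effect.
#'
#' @param site_params data.frame as returned by
#'   [synthetic_site_params()] (or the packaged copy in
#'   \code{inst/extdata/synthetic_site_params.csv}).
#' @param n_subjects subjects per replicate.
#' @param n_replicates replicates per site.
#' @param level nominal test size.
#' @param models model families to fit.
#' @param seed integer seed.
#' @return List with \code{per_site} (site-level rejection rates per
#'   model) and \code{by_decile} (median rejection rate per
#'   absolute-effect decile and model).
#' @export
run_multisite_study <- function(site_params, n_subjects = 1000L,
                                n_replicates = 100L, level = 0.05,
                                models = "rcg", seed = 1L) {
  stopifnot(nrow(site_params) >= 1)
  set.seed(seed)
  covs <- sample_covariates(n_subjects)
  X <- build_design(covs)
  gcols <- c("gamma0", "gamma_gender", "gamma_age", "gamma_bmi",
             "gamma_smoke", "gamma_depression")
  per_site <- vector("list", nrow(site_params))
  for (i in seq_len(nrow(site_params))) {
    sp <- site_params[i, ]
    gamma_true <- as.numeric(sp[gcols])
    theta <- exp(drop(X %*% gamma_true))
    rej <- setNames(numeric(length(models)), models)
    for (r in seq_len(n_replicates)) {
      b <- sample_rcg_beta(n_subjects, sp$alpha, sp$rho, theta)
      res <- .fit_and_test(b, X, models, level)
      rej <- rej + ifelse(is.na(res$reject), 0, as.numeric(res$reject))
    }
    per_site[[i]] <- data.frame(site = sp$site,
                                effect = sp$gamma_gender,
                                model = models,
                                rejection_rate = unname(rej) / n_replicates)
  }
  per_site <- do.call(rbind, per_site)
  abs_eff <- abs(per_site$effect)
  brks <- unique(quantile(abs_eff, 0:10 / 10))
  dec <- if (length(brks) < 2) rep(1L, length(abs_eff)) else
    cut(abs_eff, breaks = brks, include.lowest = TRUE, labels = FALSE)
  by_decile <- aggregate(rejection_rate ~ decile + model,
                         data = cbind(per_site, decile = dec), FUN = median)
  list(per_site = per_site, by_decile = by_decile)
}

#' Train/test log-score comparison of the three model families
#'
#' Repeatedly splits the data into disjoint training and test sets, fits
#' RCG, beta regression and M-value regression on the training part,
#' evaluates mean predictive log densities (beta-value scale) on the test
#' part, and compares models by the paired Wilcoxon signed-rank test over
#' splits.
#'
#' @param b beta values.
#' @param X design matrix.
#' @param n_splits number of train/test splits.
#' @param train_size,test_size split sizes; their sum must not exceed
#'   \code{length(b)}.
#' @param seed integer seed.
#' @param models model families to compare.
#' @return List with \code{scores} (n_splits x models matrix of mean test
#'   log-scores), \code{mean_scores}, \code{differences} (pairwise mean
#'   differences), \code{wilcoxon_p} (paired signed-rank p-values) and
#'   \code{n_dropped} (splits lost to non-convergence).
#' @export
run_logscore_study <- function(b, X, n_splits = 10L, train_size = 750L,
                               test_size = 368L, seed = 1L,
                               models = c("rcg", "betareg", "mvalue")) {
  X <- as.matrix(X)
  n <- length(b)
  if (train_size + test_size > n) stop("train + test exceeds sample size")
  set.seed(seed)
  scores <- matrix(NA_real_, n_splits, length(models),
                   dimnames = list(NULL, models))
  for (s in seq_len(n_splits)) {
    idx <- sample.int(n, train_size + test_size)
    tr <- idx[seq_len(train_size)]
    te <- idx[train_size + seq_len(test_size)]
    for (mdl in models) {
      fit <- switch(mdl,
        rcg = try(fit_rcg(b[tr], X[tr, , drop = FALSE]), silent = TRUE),
        betareg = try(fit_betareg(b[tr], X[tr, , drop = FALSE]),
                      silent = TRUE),
        mvalue = try(fit_mvalue(b[tr], X[tr, , drop = FALSE]),
                     silent = TRUE))
      if (!inherits(fit, "try-error") &&
          (is.null(fit$converged) || fit$converged))
        scores[s, mdl] <- log_score(fit, b[te], X[te, , drop = FALSE])
    }
  }
  ok <- complete.cases(scores)
  sc <- scores[ok, , drop = FALSE]
  pairs <- utils::combn(models, 2, simplify = FALSE)
  diffs <- sapply(pairs, function(pr) mean(sc[, pr[1]] - sc[, pr[2]]))
  pvals <- sapply(pairs, function(pr)
    if (nrow(sc) >= 3)
      wilcox.test(sc[, pr[1]], sc[, pr[2]], paired = TRUE)$p.value
    else NA_real_)
  names(diffs) <- names(pvals) <-
    vapply(pairs, function(pr) paste(pr, collapse = "_minus_"), "")
  list(scores = scores, mean_scores = colMeans(sc), differences = diffs,
       wilcoxon_p = pvals, n_dropped = sum(!ok))
}

#' Write a simulation result as tidy CSV
#'
#' @param result a [run_power_study()] result.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_simulation_result <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path)
  invisible(path)
}
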