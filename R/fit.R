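## Maximum-likelihood fitting of the RCG model and Wald-type tests.
##
## The likelihood is maximized over the unconstrained reparameterization
## (gamma, log alpha, logit rho) with analytic gradients; the Wald test
## uses the gamma-block of the observed information with (alpha, rho)
## plugged in at their estimates.

.default_fit_settings <- function() {
  list(maxit = 500L, reltol = 1e-9, grad_tol = 1e-5, n_restarts = 3L,
       optimizer = "bfgs", boost_step = 0.1, boost_maxit = 20000L)
}

.check_design <- function(X, n_extra = 0L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("design matrix contains non-finite values")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear columns)")
  if (nrow(X) <= ncol(X) + n_extra)
    stop("too few observations for the number of parameters")
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)",
                     paste0("x", seq_len(ncol(X) - 1L)))[seq_len(ncol(X))]
  X
}

## (gamma, log alpha, logit rho) <-> (gamma, alpha, rho). The
## unconstrained coordinates are clamped to keep alpha and rho inside
## numerically safe ranges during line searches.
.clamp_psi <- function(psi, p1) {
  psi[p1 + 1] <- min(max(psi[p1 + 1], -13), 13)
  psi[p1 + 2] <- min(max(psi[p1 + 2], -35), 35)
  psi
}

.psi_to_params <- function(psi, p1) {
  psi <- .clamp_psi(psi, p1)
  rcg_params(psi[seq_len(p1)],
             alpha = exp(psi[p1 + 1]),
             rho = min(plogis(psi[p1 + 2]), .RHO_MAX))
}

#' Starting values for the RCG optimizer
#'
#' gamma from an ordinary least-squares fit to M-values rescaled to the
#' log mean-ratio link (theta rises as methylation falls, hence the
#' factor -log 2), alpha from a method-of-moments fit of a symmetric beta
#' distribution, rho = 1/2.
#' @noRd
.rcg_init <- function(b, X) {
  mv <- mvalue_transform(b)
  ols <- lm.fit(X, mv)$coefficients
  gamma0 <- -base::log(2) * ols
  v <- var(b)
  alpha0 <- (0.25 / max(v, 1e-6) - 1) / 2
  alpha0 <- min(max(alpha0, 0.2), 500)
  rcg_params(gamma0, alpha = alpha0, rho = 0.5)
}

#' Fit the RCG regression model by maximum likelihood
#'
#' Maximizes the ratio-of-correlated-gammas log-likelihood jointly over
#' the coefficient vector \code{gamma}, the shape \code{alpha} and the
#' intensity correlation \code{rho}, using quasi-Newton (BFGS) iterations
#' on the unconstrained scale (\code{gamma}, \eqn{\log\alpha},
#' \eqn{\mathrm{logit}\,\rho}) with analytic gradients. A slower
#' coordinate-wise gradient-ascent variant (in the spirit of
#' component-wise boosting with linear base-learners, which targets the
#' same maximizer) is available via \code{settings$optimizer = "boost"}.
#' On non-convergence the optimizer is restarted up to
#' \code{settings$n_restarts} times from jittered starting values; a fit
#' that still fails is returned with \code{converged = FALSE} rather than
#' raising an error.
#'
#' @param b numeric vector of beta values in (0, 1) (clamped to
#'   \[1e-6, 1-1e-6\] if needed).
#' @param X design matrix (first column ones); see [build_design()].
#' @param init optional [rcg_params()] starting value.
#' @param settings optional list overriding the defaults: \code{maxit},
#'   \code{reltol}, \code{grad_tol}, \code{n_restarts}, \code{optimizer}
#'   (\code{"bfgs"} or \code{"boost"}).
#' @return An object of class \code{"rcg_fit"}: a list with elements
#'   \code{params} (the estimates), \code{loglik}, \code{info_gamma}
#'   (observed-information gamma-block at the maximum), \code{vcov_gamma},
#'   \code{n_obs}, \code{converged}, \code{iterations},
#'   \code{grad_norm} (scaled gradient norm at the solution), \code{X},
#'   \code{b}.
#' @examples
#' set.seed(1)
#' X <- cbind(1, rbinom(400, 1, 0.5))
#' b <- sample_rcg_beta(400, alpha = 5, rho = 0.5,
#'                      theta = exp(X %*% c(-1, 0.4)))
#' fit <- fit_rcg(b, X)
#' coef(fit)
#' @export
fit_rcg <- function(b, X, init = NULL, settings = list()) {
  settings <- modifyList(.default_fit_settings(), settings)
  X <- .check_design(X, n_extra = 2L)
  b <- clamp_beta(b, quiet = TRUE)
  if (length(b) != nrow(X)) stop("length(b) != nrow(X)")
  p1 <- ncol(X)
  if (is.null(init)) init <- .rcg_init(b, X)
  stopifnot(inherits(init, "rcg_params"), length(init$gamma) == p1)

  ## optimize on a centered/scaled copy of the covariates (intercept
  ## untouched): covariates on very different scales (age vs binary
  ## indicators) otherwise leave BFGS crawling along a ridge
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ## gamma_std = diag(scl) gamma_orig (+ intercept shift)
  to_std <- function(g) {
    gs <- g * scl
    gs[1] <- g[1] + sum(g[-1] * ctr[-1])
    gs
  }
  to_orig <- function(gs) {
    g <- gs / scl
    g[1] <- gs[1] - sum(g[-1] * ctr[-1])
    g
  }

  negll <- function(psi) {
    pr <- .psi_to_params(psi, p1)
    theta <- exp(pmin(pmax(drop(Z %*% pr$gamma), -500), 500))
    val <- -sum(.cpp_rcg_logpdf(b, pr$alpha, pr$rho, theta))
    if (!is.finite(val)) 1e10 else val
  }
  ## chain rule: d/d(log alpha) = alpha * d/dalpha;
  ## d/d(logit rho) = rho(1-rho) * d/drho
  neggr <- function(psi) {
    pr <- .psi_to_params(psi, p1)
    eta <- pmin(pmax(drop(Z %*% pr$gamma), -500), 500)
    parts <- .rcg_deriv_parts(b, eta, pr$alpha, pr$rho)
    g <- -c(drop(crossprod(Z, parts$dl_deta)),
            pr$alpha * sum(parts$dl_dalpha),
            pr$rho * (1 - pr$rho) * sum(parts$dl_drho))
    if (!all(is.finite(g))) g[] <- 0
    g
  }

  psi0 <- c(to_std(init$gamma), base::log(init$alpha),
            qlogis(min(max(init$rho, 1e-4), 0.999)))
  ll_init <- -negll(psi0)

  ## Newton ascent in gamma at fixed (alpha, rho), with step halving;
  ## used by the profile-likelihood outer optimization. The likelihood
  ## carries a long curved ridge in (alpha, rho) -- nearby (alpha, rho)
  ## pairs mimic each other's ratio distribution closely -- so the
  ## hyperparameters are profiled out rather than jointly stepped.
  newton_gamma <- function(gs, alpha, rho, max_newton = 50L) {
    f_at <- function(g) {
      theta <- exp(pmin(pmax(drop(Z %*% g), -500), 500))
      val <- sum(.cpp_rcg_logpdf(b, alpha, rho, theta))
      if (is.finite(val)) val else -1e10
    }
    f <- f_at(gs)
    for (it in seq_len(max_newton)) {
      eta <- pmin(pmax(drop(Z %*% gs), -500), 500)
      parts <- .rcg_deriv_parts(b, eta, alpha, rho)
      gr <- drop(crossprod(Z, parts$dl_deta))
      if (!all(is.finite(gr))) break
      if (max(abs(gr)) < 1e-8 * max(1, abs(f))) break
      H <- crossprod(Z, Z * parts$d2l_deta2)
      step <- tryCatch(solve(H, gr), error = function(e) gr / sqrt(sum(gr^2)))
      if (!all(is.finite(step))) step <- gr / sqrt(sum(gr^2))
      if (sum(step * gr) > 0) step <- -step   # ensure ascent direction
      lam <- 1
      repeat {
        f_new <- f_at(gs - lam * step)
        if (f_new > f - 1e-12) break
        lam <- lam / 2
        if (lam < 1e-10) break
      }
      if (f_new <= f + 1e-12) { f <- max(f, f_new); break }
      gs <- gs - lam * step
      f <- f_new
    }
    list(gamma = gs, value = f)
  }

  ## joint damped-Newton iterations over the full parameter vector with
  ## a numeric Hessian of the analytic gradient; quadratic convergence
  ## of the scaled gradient norm once inside the basin of the maximum
  newton_polish <- function(psi, max_it = 25L) {
    val <- negll(psi)
    k <- length(psi)
    evals <- 0L
    mu <- 0                      # Levenberg-Marquardt damping
    for (newton_it in seq_len(max_it)) {
      gr <- neggr(psi)
      evals <- evals + 1L
      if (.scaled_grad_norm(gr, psi) < settings$grad_tol / 10) break
      H <- matrix(0, k, k)
      for (j in seq_len(k)) {
        h <- 1e-6 * max(1, abs(psi[j]))
        ej <- (seq_len(k) == j) * h
        H[, j] <- (neggr(psi + ej) - neggr(psi - ej)) / (2 * h)
      }
      H <- (H + t(H)) / 2
      evals <- evals + 2L * k
      dscale <- mean(abs(diag(H))) + 1e-8
      improved <- FALSE
      for (try_mu in 1:20) {
        Hd <- H + mu * dscale * diag(k)
        step <- tryCatch(solve(Hd, gr), error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step)) &&
            sum(step * gr) > 0) {
          val_new <- negll(psi - step)
          if (is.finite(val_new) && val_new < val - 1e-12) {
            psi <- psi - step
            val <- val_new
            mu <- mu / 3
            improved <- TRUE
            break
          }
        }
        mu <- max(mu * 10, 1e-6)
      }
      if (!improved) break
    }
    list(par = psi, value = val, iterations = evals)
  }

  run_once <- function(psi_start, thorough = FALSE) {
    if (settings$optimizer == "boost") {
      return(.boost_optim(psi_start, negll, neggr, settings))
    }
    ## coarse grid scan over (alpha, rho) at the starting gamma picks
    ## the right segment of the (alpha, rho) ridge to start from
    g_cur <- psi_start[seq_len(p1)]
    evals <- 0L
    theta0 <- exp(pmin(pmax(drop(Z %*% g_cur), -500), 500))
    grid <- expand.grid(la = base::log(c(0.5, 2, 6, 20, 70, 250)),
                        lr = qlogis(c(0.05, 0.35, 0.65, 0.85, 0.95, 0.99)))
    gval <- mapply(function(la, lr) {
      v <- sum(.cpp_rcg_logpdf(b, exp(la), plogis(lr), theta0))
      if (is.finite(v)) v else -Inf
    }, grid$la, grid$lr)
    hp <- as.numeric(grid[which.max(gval), ])
    ## profile likelihood over (log alpha, logit rho), gamma warm-started
    ## across evaluations; by the envelope theorem the profile gradient
    ## equals the (alpha, rho) partials evaluated at the inner maximizer,
    ## so the outer 2-D search can run quasi-Newton with exact gradients
    prof <- function(hp) {
      hp <- .clamp_psi(c(g_cur, hp), p1)[p1 + 1:2]
      out <- newton_gamma(g_cur, exp(hp[1]),
                          min(plogis(hp[2]), .RHO_MAX))
      g_cur <<- out$gamma
      evals <<- evals + 1L
      -out$value
    }
    nm <- optim(hp, prof, method = "Nelder-Mead",
                control = list(maxit = 50, reltol = 1e-9))
    res <- newton_polish(c(g_cur,
                           .clamp_psi(c(g_cur, nm$par), p1)[p1 + 1:2]))
    evals <- evals + res$iterations
    if (thorough ||
        .scaled_grad_norm(neggr(res$par), res$par) >= settings$grad_tol) {
      ## longer profile search, then polish again
      g_cur <- res$par[seq_len(p1)]
      nm <- optim(res$par[p1 + 1:2], prof, method = "Nelder-Mead",
                  control = list(maxit = 200, reltol = 1e-11))
      res2 <- newton_polish(c(g_cur,
                              .clamp_psi(c(g_cur, nm$par), p1)[p1 + 1:2]))
      evals <- evals + res2$iterations
      if (res2$value < res$value) res <- res2
    }
    list(par = res$par, value = res$value, iterations = evals)
  }

  best <- NULL
  converged <- FALSE
  iters <- 0L
  for (attempt in 0:settings$n_restarts) {
    psi_start <- if (attempt == 0) psi0 else
      psi0 + rnorm(length(psi0), sd = 0.25)
    res <- try(run_once(psi_start), silent = TRUE)
    if (inherits(res, "try-error")) next
    iters <- iters + res$iterations
    if (is.null(best) || res$value < best$value) best <- res
    gn <- .scaled_grad_norm(neggr(best$par), best$par)
    if (is.finite(best$value) && gn < settings$grad_tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(best))
    stop("RCG optimization failed on all attempts")

  params <- .psi_to_params(best$par, p1)
  params$gamma <- to_orig(params$gamma)
  names(params$gamma) <- colnames(X)
  ll <- -best$value
  sh <- rcg_score_and_hessian(b, X, params, hessian = "gamma")
  info_gamma <- -sh$hessian
  dimnames(info_gamma) <- list(colnames(X), colnames(X))
  vcov_gamma <- tryCatch(solve(info_gamma), error = function(e) {
    warning("singular observed information: ", conditionMessage(e))
    matrix(NA_real_, p1, p1, dimnames = dimnames(info_gamma))
  })
  structure(list(params = params, loglik = ll,
                 info_gamma = info_gamma, vcov_gamma = vcov_gamma,
                 n_obs = length(b), converged = converged,
                 iterations = iters,
                 grad_norm = .scaled_grad_norm(neggr(best$par), best$par),
                 loglik_init = ll_init,
                 b = b, X = X, model = "rcg"),
            class = "rcg_fit")
}

.scaled_grad_norm <- function(g, psi) {
  max(abs(g) / pmax(1, abs(psi)))
}

## Coordinate-wise gradient ascent with a fixed step length: one
## coordinate (the steepest) is updated per iteration, mirroring
## component-wise boosting with linear base-learners.
.boost_optim <- function(psi, negll, neggr, settings) {
  nu <- settings$boost_step
  f <- negll(psi)
  for (it in seq_len(settings$boost_maxit)) {
    g <- neggr(psi)
    j <- which.max(abs(g))
    psi_new <- psi
    psi_new[j] <- psi[j] - nu * sign(g[j]) * min(abs(g[j]), 1)
    f_new <- negll(psi_new)
    if (!is.finite(f_new) || f_new > f - 1e-12) {
      nu <- nu / 2
      if (nu < 1e-8) break
      next
    }
    psi <- psi_new
    f <- f_new
  }
  list(par = psi, value = f, iterations = it)
}

#' Observed information for the RCG coefficients
#'
#' Returns the gamma-block of minus the Hessian of the log-likelihood at
#' the maximum-likelihood estimates. In the default mode (\code{"gamma"},
#' matching the Wald construction of the model) \code{alpha} and
#' \code{rho} are held fixed at their estimates; mode \code{"full"}
#' inverts the complete (p+3)-dimensional observed information and
#' returns the inverse of the gamma-block of the inverse, i.e. standard
#' errors that account for hyperparameter uncertainty.
#'
#' @param fit an [fit_rcg()] result with \code{converged = TRUE}.
#' @param mode \code{"gamma"} (default) or \code{"full"}.
#' @return Symmetric positive-definite matrix (p+1) x (p+1).
#' @export
observed_information <- function(fit, mode = c("gamma", "full")) {
  stopifnot(inherits(fit, "rcg_fit"))
  mode <- match.arg(mode)
  if (!fit$converged) stop("fit did not converge")
  if (mode == "gamma") return(fit$info_gamma)
  sh <- rcg_score_and_hessian(fit$b, fit$X, fit$params, hessian = "full")
  Jfull <- -sh$hessian
  p1 <- length(fit$params$gamma)
  Vfull <- tryCatch(solve(Jfull), error = function(e)
    stop("singular full observed information"))
  V_gamma <- Vfull[seq_len(p1), seq_len(p1), drop = FALSE]
  J <- solve(V_gamma)
  dimnames(J) <- dimnames(fit$info_gamma)
  (J + t(J)) / 2
}

#' Wald test for an RCG (or comparator) coefficient
#'
#' Computes the Wald statistic \eqn{Z_k = \hat\gamma_k / \sqrt{J^{-1}_{kk}}}
#' with \eqn{J} the observed information evaluated at the estimates, a
#' two-sided p-value from the standard normal reference distribution, and
#' a symmetric confidence interval.
#'
#' @param fit a converged model fit ([fit_rcg()], [fit_betareg()] or
#'   [fit_mvalue()]).
#' @param k coefficient to test: an index (1 = first covariate after the
#'   intercept) or a coefficient name. Index 0 (the intercept) is allowed
#'   but flagged, since it does not test a methylation-covariate
#'   association.
#' @param level nominal test size (default 0.05); the confidence interval
#'   has coverage \code{1 - level}.
#' @return Object of class \code{"rcg_wald"}: list with \code{coef}
#'   (label), \code{estimate}, \code{se}, \code{z}, \code{p}, \code{ci},
#'   \code{level}, \code{reject}.
#' @export
wald_test <- function(fit, k, level = 0.05) {
  est_all <- coef(fit)
  V <- vcov(fit)
  labels <- names(est_all)
  if (is.character(k)) {
    idx <- match(k, labels)
    if (is.na(idx)) stop("unknown coefficient: ", k)
  } else {
    if (k < 0 || k > length(est_all) - 1L)
      stop("coefficient index out of range")
    if (k == 0)
      warning("testing the intercept is not a methylation-association test")
    idx <- k + 1L
  }
  est <- est_all[idx]
  se <- sqrt(V[idx, idx])
  z <- if (se > 0) est / se else 0
  p <- 2 * pnorm(-abs(z))
  qz <- qnorm(1 - level / 2)
  structure(list(coef = labels[idx], estimate = unname(est),
                 se = unname(se), z = unname(z), p = unname(p),
                 ci = unname(c(est - qz * se, est + qz * se)),
                 level = level, reject = unname(p < level)),
            class = "rcg_wald")
}

#' @export
print.rcg_wald <- function(x, ...) {
  cat(sprintf("Wald test for '%s': estimate = %.5g, se = %.5g\n",
              x$coef, x$estimate, x$se))
  cat(sprintf("  z = %.4f, p = %.4g, %g%% CI [%.5g, %.5g]\n",
              x$z, x$p, 100 * (1 - x$level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
coef.rcg_fit <- function(object, ...) object$params$gamma

#' @export
vcov.rcg_fit <- function(object, ...) object$vcov_gamma

#' @export
logLik.rcg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$params$gamma) + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.rcg_fit <- function(x, ...) {
  cat("RCG model fit (ratio of correlated gammas)\n")
  cat(sprintf("  n = %d, logLik = %.3f, converged = %s\n",
              x$n_obs, x$loglik, x$converged))
  cat(sprintf("  alpha = %.4g, rho = %.4g\n", x$params$alpha, x$params$rho))
  cat("  coefficients:\n")
  print(signif(x$params$gamma, 5))
  invisible(x)
}

#' @export
summary.rcg_fit <- function(object, ...) {
  est <- coef(object)
  se <- sqrt(diag(vcov(object)))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.rcg_fit")
}

#' @export
print.summary.rcg_fit <- function(x, ...) {
  print(x$fit)
  cat("\n  Wald tests (gamma-block observed information):\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}
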