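## Comparator models: M-value (Gaussian) regression on logit2-transformed
## beta values and beta regression with a logit mean link and constant
## precision. Both expose Wald z-statistics of the same form as the RCG
## model (estimate / sqrt of inverse observed information), and both
## provide predictive log densities for log-score comparison on the beta
## scale.

#' M-value transform and its inverse
#'
#' The M-value is the base-2 logit of a beta value,
#' \eqn{\mathrm{M}(b) = \log_2(b/(1-b))}; strictly increasing on (0, 1).
#'
#' @param b beta values in (0, 1).
#' @return M-values (real line).
#' @examples
#' mvalue_transform(0.8)  # 2
#' @export
mvalue_transform <- function(b) {
  if (any(b <= 0) || any(b >= 1)) stop("'b' must lie strictly in (0, 1)")
  log2(b / (1 - b))
}

#' @rdname mvalue_transform
#' @param m M-values.
#' @export
mvalue_inverse <- function(m) {
  plogis(m * base::log(2))
}

#' Fit M-value regression
#'
#' Ordinary least squares of \eqn{\log_2(b/(1-b))} on the design matrix,
#' with the maximum-likelihood residual variance (divisor n) so that
#' Wald z-statistics are estimate over inverse-observed-information
#' standard error, referred to the standard normal.
#'
#' @param b beta values in (0, 1).
#' @param X design matrix.
#' @return Object of class \code{"mvalue_fit"} with \code{coef},
#'   \code{sigma2} (ML), \code{vcov}, \code{loglik} (on the M-value
#'   scale), \code{n_obs}, \code{converged}.
#' @export
fit_mvalue <- function(b, X) {
  X <- .check_design(X)
  b <- clamp_beta(b, quiet = TRUE)
  m <- mvalue_transform(b)
  fit <- lm.fit(X, m)
  cf <- fit$coefficients
  rss <- sum(fit$residuals^2)
  n <- length(m)
  sigma2 <- rss / n
  XtXinv <- chol2inv(chol(crossprod(X)))
  V <- sigma2 * XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  ll <- sum(dnorm(m, mean = drop(X %*% cf), sd = sqrt(sigma2), log = TRUE))
  structure(list(coef = setNames(cf, colnames(X)), sigma2 = sigma2,
                 vcov = V, loglik = ll, n_obs = n, converged = TRUE,
                 X = X, b = b, model = "mvalue"),
            class = "mvalue_fit")
}

#' @export
coef.mvalue_fit <- function(object, ...) object$coef
#' @export
vcov.mvalue_fit <- function(object, ...) object$vcov
#' @export
print.mvalue_fit <- function(x, ...) {
  cat("M-value regression fit (Gaussian on logit2 scale)\n")
  cat(sprintf("  n = %d, sigma2 (ML) = %.5g\n", x$n_obs, x$sigma2))
  print(signif(x$coef, 5))
  invisible(x)
}

#' Fit beta regression with logit mean link
#'
#' Joint maximum likelihood over the mean coefficients and a constant
#' precision \eqn{\phi}: \eqn{b_i \sim \mathrm{Beta}(\mu_i\phi,
#' (1-\mu_i)\phi)} with \eqn{\mathrm{logit}(\mu_i) = X_i^\top\gamma}, so
#' the variance is \eqn{\mu(1-\mu)/(1+\phi)}. Standard errors come from
#' the coefficient block of the observed information with \eqn{\phi}
#' plugged in at its estimate, mirroring the Wald construction used for
#' the RCG model.
#'
#' @param b beta values in (0, 1).
#' @param X design matrix.
#' @return Object of class \code{"betareg_fit"} with \code{coef},
#'   \code{phi}, \code{vcov}, \code{loglik}, \code{mu}, \code{n_obs},
#'   \code{converged}.
#' @export
fit_betareg <- function(b, X) {
  X <- .check_design(X, n_extra = 1L)
  b <- clamp_beta(b, quiet = TRUE)
  n <- length(b)
  p1 <- ncol(X)

  ## optimize on centered/scaled covariates (cf. fit_rcg)
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  to_orig <- function(gs) {
    g <- gs / scl
    g[1] <- gs[1] - sum(g[-1] * ctr[-1])
    g
  }

  negll <- function(psi) {
    mu <- plogis(drop(Z %*% psi[seq_len(p1)]))
    phi <- exp(min(max(psi[p1 + 1], -13), 13))
    val <- -sum(dbeta(b, mu * phi, (1 - mu) * phi, log = TRUE))
    if (!is.finite(val)) 1e10 else val
  }
  neggr <- function(psi) {
    mu <- plogis(drop(Z %*% psi[seq_len(p1)]))
    phi <- exp(min(max(psi[p1 + 1], -13), 13))
    lb <- base::log(b); l1b <- log1p(-b)
    Tq <- lb - l1b - digamma(mu * phi) + digamma((1 - mu) * phi)
    dl_deta <- phi * Tq * mu * (1 - mu)
    dl_dlphi <- phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                            (1 - mu) * digamma((1 - mu) * phi) +
                            mu * lb + (1 - mu) * l1b)
    g <- -c(drop(crossprod(Z, dl_deta)), dl_dlphi)
    if (!all(is.finite(g))) g[] <- 0
    g
  }

  ## starting values: OLS on the logit scale; phi by moments
  z <- qlogis(b)
  cf0 <- lm.fit(Z, z)$coefficients
  mu0 <- plogis(drop(Z %*% cf0))
  v0 <- var(b - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v0, 1e-8) - 1, 0.5)
  psi0 <- c(cf0, base::log(phi0))

  opt <- optim(psi0, negll, neggr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  ## Newton polish with a numeric Hessian of the analytic gradient
  psi <- opt$par
  val <- opt$value
  k <- p1 + 1L
  for (it in 1:10) {
    gr <- neggr(psi)
    if (.scaled_grad_norm(gr, psi) < 1e-6) break
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      h <- 1e-6 * max(1, abs(psi[j]))
      ej <- (seq_len(k) == j) * h
      H[, j] <- (neggr(psi + ej) - neggr(psi - ej)) / (2 * h)
    }
    step <- tryCatch(solve((H + t(H)) / 2, gr), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    ok <- FALSE
    for (half in 1:20) {
      vn <- negll(psi - lam * step)
      if (is.finite(vn) && vn < val - 1e-12) {
        psi <- psi - lam * step; val <- vn; ok <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!ok) break
  }
  converged <- .scaled_grad_norm(neggr(psi), psi) <
    1e-6 * max(1, abs(val))
  cf <- setNames(to_orig(psi[seq_len(p1)]), colnames(X))
  phi <- exp(psi[p1 + 1])
  mu <- plogis(drop(X %*% cf))
  ## analytic eta-block of the observed information, phi plugged in
  Tq <- base::log(b) - log1p(-b) - digamma(mu * phi) + digamma((1 - mu) * phi)
  mup <- mu * (1 - mu)
  w <- phi * (-phi * mup^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi)) +
                Tq * mup * (1 - 2 * mu))
  J <- -crossprod(X, X * w)
  V <- tryCatch(solve((J + t(J)) / 2), error = function(e)
    matrix(NA_real_, p1, p1))
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coef = cf, phi = phi, mu = mu, vcov = V,
                 loglik = -val, n_obs = n, converged = converged,
                 X = X, b = b, model = "betareg"),
            class = "betareg_fit")
}

#' @export
coef.betareg_fit <- function(object, ...) object$coef
#' @export
vcov.betareg_fit <- function(object, ...) object$vcov
#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression fit (logit link, constant precision)\n")
  cat(sprintf("  n = %d, phi = %.5g, logLik = %.3f, converged = %s\n",
              x$n_obs, x$phi, x$loglik, x$converged))
  print(signif(x$coef, 5))
  invisible(x)
}

#' Predictive log-score of a fitted model on test data
#'
#' Mean log predictive density over held-out observations, evaluated on
#' the beta-value scale for all three model families so that scores are
#' directly comparable. For the M-value model the Gaussian density on the
#' transformed scale is mapped back by the change of variables
#' \eqn{f_b(b) = f_M(\mathrm{M}(b))\,|d\mathrm{M}/db|}, i.e. the mean log
#' Jacobian \eqn{\log(1/(b(1-b)\ln 2))} is added; set
#' \code{jacobian = FALSE} to score on the raw M-value scale instead.
#'
#' @param fit a converged [fit_rcg()], [fit_betareg()] or [fit_mvalue()]
#'   object.
#' @param b_test held-out beta values in (0, 1).
#' @param X_test held-out design matrix.
#' @param jacobian include the logit2 change-of-variables term for the
#'   M-value model (default TRUE).
#' @return Scalar mean predictive log density.
#' @export
log_score <- function(fit, b_test, X_test, jacobian = TRUE) {
  X_test <- as.matrix(X_test)
  b_test <- clamp_beta(b_test, quiet = TRUE)
  if (nrow(X_test) != length(b_test)) stop("test dimensions disagree")
  if (inherits(fit, "rcg_fit")) {
    theta <- exp(drop(X_test %*% fit$params$gamma))
    mean(drcg(b_test, fit$params$alpha, fit$params$rho, theta, log = TRUE))
  } else if (inherits(fit, "betareg_fit")) {
    mu <- plogis(drop(X_test %*% fit$coef))
    mean(dbeta(b_test, mu * fit$phi, (1 - mu) * fit$phi, log = TRUE))
  } else if (inherits(fit, "mvalue_fit")) {
    m <- mvalue_transform(b_test)
    ld <- dnorm(m, mean = drop(X_test %*% fit$coef),
                sd = sqrt(fit$sigma2), log = TRUE)
    jac <- if (jacobian)
      -base::log(base::log(2)) - base::log(b_test * (1 - b_test)) else 0
    mean(ld + jac)
  } else stop("unsupported fit object")
}
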