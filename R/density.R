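## Core densities of the RCG model: the Kibble bivariate gamma for the
## signal intensities (M, U) and the induced univariate density of the
## ratio b = M/(M+U). All evaluation is done in log space.

#' Parameters of the Wicksell-Kibble bivariate gamma distribution
#'
#' Container for the parameters of the bivariate gamma distribution used to
#' model methylated/unmethylated signal intensities: a common shape
#' \code{alpha}, marginal rates \code{lambda_m} and \code{lambda_u}, and the
#' Pearson correlation \code{rho} of the pair. Marginal means are
#' \eqn{\alpha/\lambda_m} and \eqn{\alpha/\lambda_u}, marginal variances
#' \eqn{\alpha/\lambda_m^2} and \eqn{\alpha/\lambda_u^2}.
#'
#' @param alpha common shape parameter, > 0.
#' @param lambda_m rate of the methylated intensity M, > 0.
#' @param lambda_u rate of the unmethylated intensity U, > 0.
#' @param rho Pearson correlation of (M, U), in \[0, 1).
#' @return An object of class \code{"bivgamma_params"}.
#' @examples
#' bivgamma_params(alpha = 5.84, lambda_m = 1, lambda_u = 1, rho = 0.93)
#' @export
bivgamma_params <- function(alpha, lambda_m, lambda_u, rho) {
  stopifnot(length(alpha) == 1L, length(lambda_m) == 1L,
            length(lambda_u) == 1L, length(rho) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(lambda_m) || lambda_m <= 0) stop("'lambda_m' must be positive")
  if (!is.finite(lambda_u) || lambda_u <= 0) stop("'lambda_u' must be positive")
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  structure(list(alpha = alpha, lambda_m = lambda_m,
                 lambda_u = lambda_u, rho = rho),
            class = "bivgamma_params")
}

#' @export
print.bivgamma_params <- function(x, ...) {
  cat("Wicksell-Kibble bivariate gamma parameters\n")
  cat(sprintf("  alpha = %g, lambda_m = %g, lambda_u = %g, rho = %g\n",
              x$alpha, x$lambda_m, x$lambda_u, x$rho))
  invisible(x)
}

#' Parameters of the RCG regression model
#'
#' The identifiable parameter set of the ratio-of-correlated-gammas
#' regression model: coefficient vector \code{gamma} of the log mean-ratio
#' link \eqn{\log\theta = X^\top\gamma} (first entry the intercept), the
#' common gamma shape \code{alpha} and the intensity correlation \code{rho}.
#'
#' @param gamma numeric coefficient vector, intercept first.
#' @param alpha shape parameter, > 0.
#' @param rho correlation, in \[0, 1).
#' @return An object of class \code{"rcg_params"}.
#' @export
rcg_params <- function(gamma, alpha, rho) {
  gamma <- as.numeric(gamma)
  if (!all(is.finite(gamma))) stop("'gamma' must be finite")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(rho) || rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  structure(list(gamma = gamma, alpha = alpha, rho = rho),
            class = "rcg_params")
}

#' @export
print.rcg_params <- function(x, ...) {
  cat("RCG model parameters\n")
  cat("  gamma:", paste(signif(x$gamma, 5), collapse = ", "), "\n")
  cat(sprintf("  alpha = %g, rho = %g\n", x$alpha, x$rho))
  invisible(x)
}

## rho is kept strictly below 1 - 1e-6 everywhere so that the factor
## (1 - rho) in the likelihood stays bounded away from zero.
.RHO_MAX <- 1 - 1e-6

#' Clamp beta values into the open unit interval
#'
#' The ratio density is defined on (0, 1); observed beta values at exactly
#' 0 or 1 (or outside the interval by rounding) are moved to the nearest
#' point of \[eps, 1 - eps\]. The number of clamped values is reported via
#' a message when positive.
#'
#' @param b numeric vector of beta values.
#' @param eps clamping margin (default 1e-6).
#' @param quiet suppress the clamping message.
#' @return Numeric vector with values in \[eps, 1 - eps\].
#' @export
clamp_beta <- function(b, eps = 1e-6, quiet = FALSE) {
  if (!is.numeric(b)) stop("'b' must be numeric")
  if (anyNA(b)) stop("'b' contains missing values")
  n_clamped <- sum(b < eps | b > 1 - eps)
  if (n_clamped > 0 && !quiet)
    message(sprintf("clamped %d beta value(s) into [%g, %g]",
                    n_clamped, eps, 1 - eps))
  pmin(pmax(b, eps), 1 - eps)
}

#' Density of the Wicksell-Kibble bivariate gamma distribution
#'
#' Joint density of correlated signal intensities (M, U) with gamma
#' marginals of common shape \code{alpha}, rates \code{lambda_m},
#' \code{lambda_u}, and Pearson correlation \code{rho}. The Bessel factor
#' is evaluated in exponentially scaled form so the density remains finite
#' where the unscaled modified Bessel function overflows. At \code{rho = 0}
#' the density factorizes into the product of the two marginal gamma
#' densities.
#'
#' @param m,u positive intensity values (vectors are recycled).
#' @param params a [bivgamma_params()] object.
#' @param log if TRUE return the log density.
#' @return Density values (or log densities).
#' @export
dkibble <- function(m, u, params, log = FALSE) {
  stopifnot(inherits(params, "bivgamma_params"))
  if (any(m <= 0) || any(u <= 0)) stop("'m' and 'u' must be positive")
  alpha <- params$alpha; lm_ <- params$lambda_m
  lu_ <- params$lambda_u; rho <- params$rho
  if (rho < 1e-12) {
    ld <- dgamma(m, shape = alpha, rate = lm_, log = TRUE) +
      dgamma(u, shape = alpha, rate = lu_, log = TRUE)
  } else {
    z <- 2 * sqrt(rho * lm_ * lu_ * m * u) / (1 - rho)
    ## besselI(..., expon.scaled) returns I_nu(z) * exp(-z)
    ld <- alpha * (base::log(lm_) + base::log(lu_)) -
      base::log(1 - rho) - lgamma(alpha) +
      (alpha - 1) / 2 * (base::log(m * u) - base::log(rho * lm_ * lu_)) -
      (lm_ * m + lu_ * u) / (1 - rho) +
      base::log(besselI(z, nu = alpha - 1, expon.scaled = TRUE)) + z
  }
  if (log) ld else exp(ld)
}

#' Density of the ratio of correlated gammas (RCG density)
#'
#' Density of \eqn{b = M/(M+U)} when (M, U) follow the Wicksell-Kibble
#' bivariate gamma distribution with common shape \code{alpha} and
#' correlation \code{rho}. Only the rate ratio
#' \eqn{\theta = \lambda_m/\lambda_u} is identifiable from the ratio, so
#' the density is parameterized by \code{theta} directly (internally
#' \eqn{\lambda_m = \theta}, \eqn{\lambda_u = 1}). At \code{rho = 0},
#' \code{theta = 1} the distribution reduces to Beta(alpha, alpha); the
#' density obeys the reflection identity
#' \eqn{f(b; \alpha, \rho, \theta) = f(1-b; \alpha, \rho, 1/\theta)}.
#'
#' @param b values in the open interval (0, 1).
#' @param alpha common gamma shape, > 0.
#' @param rho intensity correlation, in \[0, 1).
#' @param theta mean-intensity ratio \eqn{E(U)/E(M)}, > 0 (vector recycled
#'   against \code{b}).
#' @param log if TRUE return the log density.
#' @return Density values (or log densities).
#' @examples
#' drcg(0.5, alpha = 2, rho = 0, theta = 1)   # Beta(2,2) density at 1/2
#' @export
drcg <- function(b, alpha, rho, theta, log = FALSE) {
  if (any(b <= 0) || any(b >= 1)) stop("'b' must lie strictly in (0, 1)")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("'theta' must be positive")
  if (!is.finite(rho) || rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  rho <- min(rho, .RHO_MAX)
  if (length(theta) != 1L && length(theta) != length(b)) {
    n <- max(length(b), length(theta))
    b <- rep_len(b, n)
    theta <- rep_len(theta, n)
  }
  ld <- .cpp_rcg_logpdf(b, alpha, rho, theta)
  if (log) ld else exp(ld)
}

#' Log-likelihood of the RCG regression model
#'
#' Sum over observations of the log ratio density with per-observation
#' mean ratio \eqn{\theta_i = \exp(X_i^\top\gamma)}.
#'
#' @param b numeric vector of beta values in (0, 1).
#' @param X design matrix with leading column of ones, \code{nrow(X) ==
#'   length(b)}.
#' @param params an [rcg_params()] object with \code{length(gamma) ==
#'   ncol(X)}.
#' @return Scalar log-likelihood.
#' @export
rcg_loglik <- function(b, X, params) {
  stopifnot(inherits(params, "rcg_params"))
  X <- as.matrix(X)
  if (nrow(X) != length(b))
    stop("dimension mismatch: length(b) != nrow(X)")
  if (ncol(X) != length(params$gamma))
    stop("dimension mismatch: ncol(X) != length(gamma)")
  theta <- exp(drop(X %*% params$gamma))
  ll <- drcg(b, params$alpha, params$rho, theta, log = TRUE)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1L]
    stop(sprintf("non-finite log-likelihood contribution at observation %d",
                 bad))
  }
  sum(ll)
}

## Per-observation pieces of the analytic derivatives, on the linear
## predictor scale eta_i = X_i' gamma. Returns:
##   dl_deta  : d l_i / d eta_i
##   d2l_deta2: d^2 l_i / d eta_i^2
##   dl_dalpha, dl_drho: per-observation partials
.rcg_deriv_parts <- function(b, eta, alpha, rho) {
  .cpp_rcg_parts(b, eta, alpha, rho)
}

#' Score vector and Hessian of the RCG log-likelihood
#'
#' Analytic gradient of the log-likelihood with respect to
#' (\code{gamma}, \code{alpha}, \code{rho}) and the analytic
#' \code{gamma}-block of the Hessian. The full (p+3)-dimensional Hessian,
#' when requested, is obtained by central differences of the analytic
#' gradient. Evaluation exactly at \code{rho = 0} triggers a boundary
#' warning and a one-sided difference in the \code{rho} direction of the
#' full Hessian.
#'
#' @param b beta values in (0, 1).
#' @param X design matrix.
#' @param params an [rcg_params()] object.
#' @param hessian one of \code{"gamma"} (analytic gamma-block, default),
#'   \code{"full"} (numeric over all parameters) or \code{"none"}.
#' @return List with \code{gradient} (named: gamma coefficients, alpha,
#'   rho) and \code{hessian} (matrix or NULL).
#' @export
rcg_score_and_hessian <- function(b, X, params,
                                  hessian = c("gamma", "full", "none")) {
  stopifnot(inherits(params, "rcg_params"))
  hessian <- match.arg(hessian)
  X <- as.matrix(X)
  eta <- drop(X %*% params$gamma)
  at_boundary <- params$rho <= 0
  if (at_boundary)
    warning("evaluating derivatives at the rho = 0 boundary")
  parts <- .rcg_deriv_parts(b, eta, params$alpha, params$rho)
  g_gamma <- drop(crossprod(X, parts$dl_deta))
  grad <- c(g_gamma, alpha = sum(parts$dl_dalpha), rho = sum(parts$dl_drho))
  cn <- colnames(X)
  if (!is.null(cn)) names(grad)[seq_along(cn)] <- cn
  H <- NULL
  if (hessian == "gamma") {
    H <- crossprod(X, X * parts$d2l_deta2)
    H <- (H + t(H)) / 2
  } else if (hessian == "full") {
    H <- .rcg_numeric_hessian(b, X, params, one_sided_rho = at_boundary)
  }
  list(gradient = grad, hessian = H)
}

## Central-difference Hessian of the log-likelihood over (gamma, alpha,
## rho), built from the analytic gradient. Steps are relative; rho uses a
## one-sided difference at the lower boundary.
.rcg_numeric_hessian <- function(b, X, params, one_sided_rho = FALSE) {
  psi <- c(params$gamma, params$alpha, params$rho)
  p1 <- length(params$gamma)
  k <- length(psi)
  grad_at <- function(v) {
    alpha <- max(v[p1 + 1], 1e-8)
    rho <- min(max(v[p1 + 2], 0), .RHO_MAX)
    pr <- rcg_params(v[seq_len(p1)], alpha, rho)
    eta <- drop(X %*% pr$gamma)
    parts <- .rcg_deriv_parts(b, eta, pr$alpha, pr$rho)
    c(drop(crossprod(X, parts$dl_deta)), sum(parts$dl_dalpha),
      sum(parts$dl_drho))
  }
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-5 * max(1, abs(psi[j]))
    if (j == k && one_sided_rho) {
      gp <- grad_at(psi + h * (seq_len(k) == j))
      g0 <- grad_at(psi)
      H[, j] <- (gp - g0) / h
    } else {
      if (j == k) h <- min(h, (.RHO_MAX - psi[k]) / 2, psi[k] / 2 + 1e-12)
      gp <- grad_at(psi + h * (seq_len(k) == j))
      gm <- grad_at(psi - h * (seq_len(k) == j))
      H[, j] <- (gp - gm) / (2 * h)
    }
  }
  (H + t(H)) / 2
}
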