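## Independent oracles used to check the package implementation. These
## deliberately re-derive quantities from first principles (naive direct
## formulas, series expansions, finite differences) and never call the
## package's own computational path.

## Ratio density computed directly from the closed-form expression with
## lambda_m = theta, lambda_u = 1 (naive arithmetic, no log-space tricks)
drcg_oracle <- function(b, alpha, rho, theta) {
  lm_ <- theta; lu_ <- 1
  t_ <- lm_ * b + lu_ * (1 - b)
  num <- gamma(2 * alpha) / gamma(alpha)^2 * (lm_ * lu_)^alpha *
    (1 - rho)^alpha * (b * (1 - b))^(alpha - 1) * t_
  den <- (t_^2 - 4 * rho * lm_ * lu_ * b * (1 - b))^(alpha + 0.5)
  num / den
}

## Modified Bessel function of the first kind by direct series summation,
## truncated when terms fall below machine precision
bessel_i_series <- function(z, nu, max_terms = 500L) {
  total <- 0
  for (k in 0:max_terms) {
    term <- exp((2 * k + nu) * log(z / 2) - lgamma(k + 1) - lgamma(k + nu + 1))
    total <- total + term
    if (k > 2 && term < .Machine$double.eps * total) break
  }
  total
}

## Kibble bivariate gamma density straight from its defining expression,
## using the series Bessel evaluation above
dkibble_oracle <- function(m, u, alpha, lambda_m, lambda_u, rho) {
  z <- 2 * sqrt(rho * lambda_m * lambda_u * m * u) / (1 - rho)
  (lambda_m * lambda_u)^alpha / ((1 - rho) * gamma(alpha)) *
    (m * u / (rho * lambda_m * lambda_u))^((alpha - 1) / 2) *
    exp(-(lambda_m * m + lambda_u * u) / (1 - rho)) *
    bessel_i_series(z, alpha - 1)
}

## central-difference gradient of f at x
num_grad <- function(f, x, h_rel = 1e-6) {
  vapply(seq_along(x), function(j) {
    h <- h_rel * max(1, abs(x[j]))
    e <- (seq_along(x) == j) * h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

## Kendall's tau without ties via inversion counting (O(n log n)):
## sort by x, count discordant pairs as inversions in the y-order
kendall_tau_fast <- function(x, y) {
  y <- y[order(x)]
  count_inv <- function(v) {
    n <- length(v)
    if (n < 2) return(list(v = v, inv = 0))
    mid <- n %/% 2
    L <- count_inv(v[1:mid])
    R <- count_inv(v[(mid + 1):n])
    merged <- numeric(n)
    inv <- L$inv + R$inv
    i <- 1L; j <- 1L
    for (k in 1:n) {
      if (i <= length(L$v) &&
          (j > length(R$v) || L$v[i] <= R$v[j])) {
        merged[k] <- L$v[i]; i <- i + 1L
      } else {
        merged[k] <- R$v[j]; j <- j + 1L
        inv <- inv + (length(L$v) - i + 1L)
      }
    }
    list(v = merged, inv = inv)
  }
  n <- length(y)
  ninv <- count_inv(y)$inv
  1 - 4 * ninv / (n * (n - 1))
}

## mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

## hand-coded Benjamini-Hochberg / Benjamini-Yekutieli step-up adjustment
fdr_stepup_oracle <- function(p, by = FALSE) {
  m <- length(p)
  o <- order(p)
  cm <- if (by) sum(1 / seq_len(m)) else 1
  adj <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

## reference effect sizes used across tests (single-site ML estimates:
## intercept, gender, age, bmi, smoke, depression)
ref_gamma <- c(-1.099, 0.096, -0.007, -0.004, 0.003, 0.001)
ref_alpha <- 5.84
ref_rho <- 0.93

## small fixed design: intercept + one binary + one continuous covariate
make_test_design <- function(n, seed = 1) {
  set.seed(seed)
  cbind("(Intercept)" = 1, gender = rbinom(n, 1, 0.5),
        age = rnorm(n, 58, 7))
}
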