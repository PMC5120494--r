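test_that("Kibble sampler reproduces moments and correlation", {
  p <- bivgamma_params(ref_alpha, 1, 1, ref_rho)
  mu <- sample_kibble(1e6, p, seed = 7)
  expect_lt(abs(mean(mu[, 1]) - ref_alpha), 0.02)
  expect_lt(abs(mean(mu[, 2]) - ref_alpha), 0.02)
  expect_lt(abs(cor(mu[, 1], mu[, 2]) - ref_rho), 0.005)
  ## marginal fidelity: Kolmogorov distance to the gamma marginals
  ks_m <- max(abs(pgamma(sort(mu[, 1]), ref_alpha, 1) -
                    seq_along(mu[, 1]) / nrow(mu)))
  ks_u <- max(abs(pgamma(sort(mu[, 2]), ref_alpha, 1) -
                    seq_along(mu[, 2]) / nrow(mu)))
  expect_lt(ks_m, 0.005)
  expect_lt(ks_u, 0.005)
})

test_that("Kibble sampler at rho = 0 gives independent pairs", {
  p <- bivgamma_params(2, 1, 2, 0)
  mu <- sample_kibble(1e4, p, seed = 8)
  expect_lt(abs(cor(mu[, 1], mu[, 2])), 3 / sqrt(1e4))
  expect_error(bivgamma_params(2, 1, 2, 1), "rho")
})

test_that("ratio of Kibble pairs follows the analytic ratio density", {
  ## ties the bivariate density to the univariate ratio density
  b <- sample_rcg_beta(1e6, ref_alpha, ref_rho, exp(-1.099), seed = 9)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 8001)
  f <- drcg(grid, ref_alpha, ref_rho, exp(-1.099))
  h <- diff(grid)[1]
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * h))
  cdf <- cdf / max(cdf)
  emp <- ecdf(b)(grid)
  expect_lt(max(abs(emp - cdf)), 0.005)
})

test_that("ratio sampler hits closed-form special cases", {
  b <- sample_rcg_beta(1e4, 1, 0, 1, seed = 10)
  expect_lt(ks.test(b, punif)$statistic, 0.02)
  b2 <- sample_rcg_beta(1e4, 2, 0, 1, seed = 11)
  expect_gt(ks.test(b2, pbeta, 2, 2)$p.value, 0.01)
})

test_that("pair-ratio and inverse-CDF sampling agree in distribution", {
  b1 <- sample_rcg_beta(1e4, 2, 0.5, 1.5, seed = 12)
  b2 <- sample_rcg_beta(1e4, 2, 0.5, 1.5, seed = 13,
                        method = "inverse_cdf")
  expect_gt(suppressWarnings(ks.test(b1, b2)$p.value), 0.01)
  ## the numeric quantile function inverts the analytic CDF accurately
  qf <- rcgmeth:::.rcg_quantile_grid(2, 0.5, 1.5)
  ps <- seq(0.05, 0.95, by = 0.05)
  cdf_at <- vapply(qf(ps), function(q)
    integrate(function(x) drcg(x, 2, 0.5, 1.5), 0, q,
              rel.tol = 1e-9)$value, 0)
  expect_lt(max(abs(cdf_at - ps)), 5e-4)
})

test_that("per-observation theta values are honoured by the sampler", {
  theta <- c(rep(0.2, 5e4), rep(5, 5e4))
  b <- sample_rcg_beta(1e5, 3, 0.5, theta, seed = 14)
  ## theta = E(U)/E(M): small theta means high methylation
  expect_gt(mean(b[1:5e4]), 0.7)
  expect_lt(mean(b[5e4 + 1:5e4]), 0.3)
})

test_that("Gumbel copula sampler matches the Kendall tau identity", {
  for (rt in c(1.5, 2, 4)) {
    uu <- rcgmeth:::.with_seed(31, rcgmeth:::.rgumbel_copula(1e5, rt))
    expect_lt(abs(kendall_tau_fast(uu[, 1], uu[, 2]) - (1 - 1 / rt)), 0.01)
    ## margins uniform
    expect_lt(ks.test(uu[, 1], punif)$statistic, 0.01)
  }
  uu0 <- rcgmeth:::.with_seed(32, rcgmeth:::.rgumbel_copula(1e4, 1))
  expect_lt(abs(cor(uu0[, 1], uu0[, 2])), 3 / sqrt(1e4))
})

test_that("copula calibration is monotone, reproducible and on target", {
  expect_identical(calibrate_copula(0, 20.2, 12.760), 1)
  rts <- vapply(c(0.2, 0.5, 0.93), function(r)
    calibrate_copula(r, 20.2, 12.760, seed = 5), 0)
  expect_true(all(diff(rts) > 0))
  rt2 <- calibrate_copula(0.5, 20.2, 12.760, seed = 5)
  expect_equal(rts[2], rt2, tolerance = 5e-4)
  ## realized gamma-scale correlation at fixed rates is on target
  set.seed(41)
  uu <- rcgmeth:::.rgumbel_copula(2e5, rts[2])
  cc <- cor(qgamma(uu[, 1], 20.2), qgamma(uu[, 2], 12.760))
  expect_lt(abs(cc - 0.5), 0.01)
})

test_that("copula intensity pairs respect covariate-dependent rates", {
  X <- make_test_design(2000)
  zm <- c(-1, 0.3, 0)
  zu <- c(-0.5, 0, 0)
  cd <- copula_design(2, 20.2, 12.760, zm, zu)
  mu <- sample_gumbel_pair(2000, cd, X, seed = 15)
  expect_true(all(mu > 0))
  ## E(M | X) = alpha_m / exp(X'zm); check the two gender groups
  g <- X[, "gender"] == 1
  expect_equal(mean(mu[g, 1]) / mean(mu[!g, 1]), exp(-0.3),
               tolerance = 0.1)
  expect_error(copula_design(0.5, 1, 1, 0, 0), "rho_tilde")
})

test_that("copula path reduces to the analytic ratio law when independent", {
  ## rho_tilde = 1, equal shapes: b = M/(M+U) must follow the rho = 0
  ## ratio density with theta = lambda_m / lambda_u
  X <- matrix(1, 2e4, 1)
  cd <- copula_design(1, 3, 3, base::log(1.5), 0)
  mu <- sample_gumbel_pair(2e4, cd, X, seed = 16)
  b <- mu[, 1] / (mu[, 1] + mu[, 2])
  grid <- seq(0.002, 0.998, length.out = 300)
  cdf <- cumsum(drcg(grid, 3, 0, 1.5)) * diff(grid)[1]
  expect_lt(max(abs(ecdf(b)(grid) - cdf / max(cdf))), 0.015)
})

test_that("synthetic covariates reproduce the cohort marginals", {
  covs <- sample_covariates(1e5, seed = 17)
  expect_lt(abs(mean(covs$gender) - 0.479), 0.005)
  expect_lt(abs(mean(covs$smoke) - 0.189), 0.005)
  expect_lt(abs(mean(covs$age) - truncnorm_mean(58.3, 7.3, 45, 75)), 0.1)
  expect_true(all(covs$age >= 45 & covs$age <= 75))
  expect_true(all(covs$bmi >= 15))
  q <- quantile(covs$depression, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), c(3, 6, 10), tolerance = 1)
  ## reproducibility: identical draw under the same seed
  expect_identical(covs, sample_covariates(1e5, seed = 17))
})

test_that("covariate specs round-trip through YAML config files", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("gender:", "  type: binary", "  prevalence: 0.479",
               "age:", "  type: normal", "  mean: 58.3", "  sd: 7.3",
               "  lower: 45", "  upper: 75"), path)
  spec <- read_covariate_spec(path)
  covs <- sample_covariates(500, spec, seed = 18)
  expect_named(covs, c("gender", "age"))
  expect_true(all(covs$gender %in% 0:1))
  writeLines(c("x:", "  type: cauchy"), path)
  expect_error(read_covariate_spec(path), "unknown type")
})

test_that("design builder prepends an intercept and dummy-codes factors", {
  df <- data.frame(g = factor(c("a", "b", "a")), x = c(1, 2, 3))
  X <- build_design(df)
  expect_equal(colnames(X), c("(Intercept)", "gb", "x"))
  expect_equal(X[, 1], c(1, 1, 1), ignore_attr = TRUE)
  expect_error(build_design(df, select = "missing"), "unknown covariate")
})
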