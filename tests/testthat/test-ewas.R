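## helpers building small delimited fixtures on the fly
write_toy_files <- function(n_sites = 3, n_samples = 4, dir = tempdir(),
                            betas = NULL) {
  samples <- paste0("s", seq_len(n_samples))
  sites <- paste0("cg", seq_len(n_sites))
  if (is.null(betas)) {
    set.seed(100)
    betas <- matrix(runif(n_sites * n_samples, 0.2, 0.8), n_sites,
                    dimnames = list(sites, samples))
  }
  covs <- data.frame(sample_id = samples,
                     gender = rep_len(0:1, n_samples),
                     age = seq(50, by = 2, length.out = n_samples))
  bp <- file.path(dir, "betas.tsv")
  cp <- file.path(dir, "covs.tsv")
  write.table(cbind(site = sites, as.data.frame(betas)), bp, sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(covs, cp, sep = "\t", row.names = FALSE, quote = FALSE)
  list(betas = bp, covs = cp, mat = betas, cov_df = covs)
}

test_that("delimited beta matrices and covariates load aligned", {
  fx <- write_toy_files()
  ds <- read_dataset(fx$betas, fx$covs)
  expect_equal(dim(ds), c(3L, 4L))
  expect_equal(rownames(ds$betas), paste0("cg", 1:3))
  expect_equal(unname(ds$betas), unname(fx$mat))
  expect_equal(names(ds$covariates), c("gender", "age"))
})

test_that("beta values are reconstructed from intensities with the offset", {
  dir <- tempdir()
  samples <- paste0("s", 1:3)
  M <- matrix(100, 2, 3, dimnames = list(c("cg1", "cg2"), samples))
  U <- M
  for (nm in c("m", "u"))
    write.table(cbind(site = rownames(M), as.data.frame(M)),
                file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  covs <- data.frame(sample_id = samples, x = 1:3)
  write.table(covs, file.path(dir, "c.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ds <- read_dataset(covariate_path = file.path(dir, "c.tsv"),
                     m_path = file.path(dir, "m.tsv"),
                     u_path = file.path(dir, "u.tsv"), offset = 100)
  expect_equal(unname(ds$betas), matrix(1 / 3, 2, 3))
  ds0 <- read_dataset(covariate_path = file.path(dir, "c.tsv"),
                      m_path = file.path(dir, "m.tsv"),
                      u_path = file.path(dir, "u.tsv"), offset = 0)
  expect_equal(unname(ds0$betas), matrix(1 / 2, 2, 3))
})

test_that("sample mismatches are dropped below threshold, fatal above", {
  fx <- write_toy_files(n_samples = 12)
  covs <- read.delim(fx$covs)
  write.table(covs[-1, ], fx$covs, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_warning(ds <- read_dataset(fx$betas, fx$covs), "unmatched")
  expect_equal(ncol(ds$betas), 11L)
  write.table(covs[1:5, ], fx$covs, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_dataset(fx$betas, fx$covs), "unmatched")
})

test_that("sites with too many missing values are refused", {
  m <- matrix(runif(40, 0.3, 0.7), 2, 20,
              dimnames = list(c("cg1", "cg2"), paste0("s", 1:20)))
  m[1, 1:3] <- NA
  covs <- data.frame(sample_id = paste0("s", 1:20), x = rnorm(20))
  expect_error(methylation_dataset(m, covs), "missing")
})

test_that("BH and BY step-up adjustments match hand-computed values", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_fdr(p, "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(p, "BY"), pmin(c(0.03, 0.03, 0.03) *
                                           (1 + 1 / 2 + 1 / 3), 1))
  expect_equal(adjust_fdr(0.04, "BH"), 0.04)
  expect_identical(adjust_fdr(numeric(0), "BH"), numeric(0))
  expect_error(adjust_fdr(c(0.5, 1.2)), "outside")
})

test_that("FDR adjustment matches an independent step-up implementation", {
  set.seed(33)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p, "BH"), fdr_stepup_oracle(p),
                 tolerance = 1e-12)
    expect_equal(adjust_fdr(p, "BY"), fdr_stepup_oracle(p, by = TRUE),
                 tolerance = 1e-12)
  }
})

make_sim_dataset <- function(n_sites, n_samples, n_true = 0, seed = 50,
                             effect = 0.5, rho = 0.8) {
  set.seed(seed)
  covs <- sample_covariates(n_samples)
  X <- build_design(covs)
  g0 <- c(-0.5, 0, -0.003, 0.002, 0.001, 0)
  betas <- matrix(NA_real_, n_sites, n_samples,
                  dimnames = list(sprintf("cg%04d", seq_len(n_sites)),
                                  paste0("s", seq_len(n_samples))))
  for (i in seq_len(n_sites)) {
    g <- g0
    if (i <= n_true) g[2] <- effect
    betas[i, ] <- sample_rcg_beta(n_samples, 5, rho, exp(drop(X %*% g)))
  }
  rownames(covs) <- colnames(betas)
  methylation_dataset(betas, covs)
}

test_that("site-wise RCG analysis ranks true-effect sites first", {
  ds <- make_sim_dataset(30, 250, n_true = 6)
  res <- run_sitewise(ds, "rcg", test = "gender")
  expect_equal(nrow(res), 30)
  expect_equal(names(res)[1:8], c("site", "coef", "estimate", "se", "z",
                                  "p", "q_bh", "q_by"))
  true_sites <- sprintf("cg%04d", 1:6)
  ranks <- rank(res$p)[res$site %in% true_sites]
  expect_lt(mean(ranks), 10)
  ## BY is never below BH, both within [0, 1]
  expect_true(all(res$q_by >= res$q_bh - 1e-12, na.rm = TRUE))
  expect_true(all(res$q_bh >= res$p - 1e-12, na.rm = TRUE))
})

test_that("site order does not affect per-site results", {
  ds <- make_sim_dataset(10, 150, n_true = 2, seed = 51)
  res1 <- run_sitewise(ds, "mvalue", test = "gender")
  perm <- c(7, 2, 9, 1, 10, 3, 8, 5, 4, 6)
  ds2 <- methylation_dataset(ds$betas[perm, ], ds$covariates)
  res2 <- run_sitewise(ds2, "mvalue", test = "gender")
  res2 <- res2[match(res1$site, res2$site), ]
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("a single-site dataset reduces to a direct fit and Wald test", {
  ds <- make_sim_dataset(1, 200, seed = 52)
  res <- run_sitewise(ds, "rcg", test = "gender")
  X <- build_design(ds$covariates)
  fit <- fit_rcg(clamp_beta(as.numeric(ds$betas[1, ]), quiet = TRUE), X)
  wt <- wald_test(fit, "gender")
  expect_equal(res$estimate, wt$estimate, tolerance = 1e-6)
  expect_equal(res$z, wt$z, tolerance = 1e-6)
  expect_equal(res$q_bh, res$p)
})

test_that("null sites produce approximately uniform p-values", {
  ds <- make_sim_dataset(120, 120, n_true = 0, seed = 53, rho = 0.5)
  res <- run_sitewise(ds, "rcg", test = "gender")
  p <- res$p[res$converged]
  expect_gt(length(p), 100)
  expect_gt(ks.test(p, punif)$p.value, 0.01)
})

test_that("all three model backends run site-wise and serialize", {
  ds <- make_sim_dataset(4, 150, n_true = 1, seed = 54)
  for (mdl in c("rcg", "betareg", "mvalue")) {
    res <- run_sitewise(ds, mdl, test = "gender")
    expect_equal(unique(res$model), mdl)
    expect_true(all(is.finite(res$p[res$converged])))
  }
  res <- run_sitewise(ds, "mvalue", test = c("gender", "age"))
  expect_equal(nrow(res), 8)
  path <- tempfile(fileext = ".tsv")
  write_ewas_results(res, path)
  back <- read.delim(path)
  expect_equal(back$p, res$p, tolerance = 1e-9)
})

test_that("the command-line interface runs end to end deterministically", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "rcgmeth", package = "rcgmeth")
  expect_true(nzchar(cli))
  fx <- write_toy_files(n_sites = 2, n_samples = 60,
                        betas = matrix(runif(120, 0.3, 0.7), 2,
                                       dimnames = list(c("cg1", "cg2"),
                                                       paste0("s", 1:60))))
  rlibs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out1 <- tempfile(fileext = ".tsv")
  out2 <- tempfile(fileext = ".tsv")
  run_cli <- function(args) {
    system2(file.path(R.home("bin"), "Rscript"), c(cli, args),
            stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", rlibs))
  }
  for (out in c(out1, out2))
    run_cli(c("ewas", "--model", "mvalue", "--betas", fx$betas,
              "--covars", fx$covs, "--test", "gender",
              "--seed", "1", "--out", out))
  expect_identical(readLines(out1), readLines(out2))
  tab <- read.delim(out1)
  expect_equal(nrow(tab), 2)
  ## simulate subcommand emits a rejection-rate table
  out3 <- tempfile(fileext = ".csv")
  run_cli(c("simulate", "--design", "part1_null", "--rho", "0.5",
            "--replicates", "2", "--n", "150", "--seed", "1",
            "--out", out3))
  sim <- read.csv(out3)
  expect_true("rejection_rate" %in% names(sim))
})
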