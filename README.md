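# rcgmeth

Regression for DNA-methylation **beta values** built on a bivariate
gamma model of the underlying signal intensities.

## Why

Illumina arrays report methylation at a CpG site as the beta value
*b = M/(M+U+a)*, where *M* and *U* are methylated and unmethylated
fluorescence intensities. Epigenome-wide association studies (EWAS) fit
site-wise regressions of *b* on covariates. The two standard tools both
lean on an assumption that real data violate: M-value regression assumes
the logit-transformed values are Gaussian, and beta regression assumes
*M* and *U* are **independent** gammas — yet on real arrays the two
intensities are strongly positively correlated.

`rcgmeth` implements the **RCG (ratio of correlated gammas) model**: the
pair (*M*, *U*) follows the Wicksell–Kibble bivariate gamma distribution
with common shape α, rates λ<sub>m</sub>, λ<sub>u</sub> and Pearson
correlation ρ ∈ [0, 1). The ratio *b = M/(M+U)* then has the closed-form
density

f(b) = Γ(2α)/Γ²(α) · (λ<sub>m</sub>λ<sub>u</sub>)<sup>α</sup>(1−ρ)<sup>α</sup>(b(1−b))<sup>α−1</sup> ·
(λ<sub>m</sub>b+λ<sub>u</sub>(1−b)) / [(λ<sub>m</sub>b+λ<sub>u</sub>(1−b))² − 4ρλ<sub>m</sub>λ<sub>u</sub>b(1−b)]<sup>α+1/2</sup>,

identifiable through the mean ratio θ = λ<sub>m</sub>/λ<sub>u</sub> =
E(U)/E(M). Covariates enter by log θ = Xᵀγ, and "γ<sub>k</sub> = 0"
means covariate *k* moves both intensities equally — no methylation
association. Maximum-likelihood fitting over (γ, α, ρ) yields Wald tests
Z<sub>k</sub> = γ̂<sub>k</sub>/√(J⁻¹)<sub>kk</sub> from the observed
information. At ρ = 0 the model collapses to beta regression, which it
contains as a special case.

The package also provides self-contained comparators (beta regression,
M-value regression) with Wald tests of the same form, predictive
log-score model comparison, exact samplers (Kibble pairs via the Poisson
mixture representation, the ratio density, a Gumbel-copula
misspecification generator, cohort-like synthetic covariates), a
power/type-I-error simulation harness, and a site-wise EWAS pipeline
with BH/BY FDR control plus a small CLI.

## Worked example

Simulate one CpG site for 500 subjects with cohort-like covariates, a
gender effect of 0.12 on log θ, shape α = 5.84 and intensity correlation
ρ = 0.93, then fit and test:

```r
library(rcgmeth)
covariates <- sample_covariates(500, seed = 42)
X <- build_design(covariates)
truth <- reference_site_params()
gamma <- truth$gamma; gamma["gender"] <- 0.12
b <- sample_rcg_beta(500, truth$alpha, truth$rho,
                     exp(drop(X %*% gamma)), seed = 43)
fit <- fit_rcg(b, X)
summary(fit)
```

```
RCG model fit (ratio of correlated gammas)
  n = 500, logLik = 1135.283, converged = TRUE
  alpha = 13.69, rho = 0.8069
  coefficients:
(Intercept)      gender         age         bmi       smoke  depression
 -1.0789000   0.1118700  -0.0074302  -0.0039232   0.0310580   0.0021330

  Wald tests (gamma-block observed information):
              Estimate Std. Error  z value   Pr(>|z|)
(Intercept) -1.0789000  0.0799200 -13.5000 1.5693e-41
gender       0.1118700  0.0156050   7.1692 7.5444e-13
age         -0.0074302  0.0011999  -6.1923 5.9290e-10
...
```

The gender estimate 0.112 (true value 0.12) is recovered within one
standard error; z = 7.17 rejects "no association" decisively. Positive γ
means methylation *decreases* with the covariate (θ = E(U)/E(M) rises).
The (α̂, ρ̂) pair sits on a likelihood ridge of nearly equivalent ratio
laws — at n = 500 the two hyperparameters are only weakly identified
jointly, which does not disturb γ, its standard error or the test.

Whole-matrix analysis and multiple testing:

```r
ds  <- read_dataset("betas.tsv", "covariates.tsv")
res <- run_sitewise(ds, model = "rcg", test = "gender")
head(res[order(res$p), ])   # site, estimate, se, z, p, q_bh, q_by, ...
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/rcgmeth ewas --model rcg --betas betas.tsv \
    --covars covariates.tsv --test gender --out results.tsv
Rscript inst/cli/rcgmeth simulate --design part1_null --rho 0.93 \
    --replicates 1000 --seed 1 --out rates.csv
```

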