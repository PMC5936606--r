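# jointbridge

Joint maximum-likelihood analysis of two correlated three-category
perinatal outcomes — gestational-age class (preterm / term / postterm)
and birth-weight class (LBW / normal / macrosomia) — for mothers nested
in maternity hospitals.  Written for perinatal epidemiologists and
biostatisticians who need odds ratios for *both* outcomes that respect
the hospital clustering and the outcome–outcome association, and for
methodologists studying random-effect laws with marginal odds-ratio
interpretation.

## The model

Each outcome follows a baseline-category (nominal) logit sub-model with
a hospital-level random intercept:

    log P(y1 = c) / P(y1 = term)   = u1_i + omega_c + x' alpha_c     c in {preterm, postterm}
    log P(y2 = c) / P(y2 = normal) = u2_i + theta_c + z' beta_c      c in {LBW, macrosomia}

The intercept pair (u1_i, u2_i) follows a bivariate Bridge
distribution: Bridge(phi_k) margins coupled by a Gaussian copula with
correlation rho.  The Bridge law is the logit-link random-effect
distribution for which marginalizing the intercept keeps the model
logistic, with every coefficient attenuated by phi —

    ∫ expit(u + eta) f(u; phi) du = expit(phi * eta)

— so exp(alpha_c) has the same odds-ratio interpretation within and
between hospitals.  The marginal likelihood is evaluated by per-cluster
adaptive Gauss–Hermite quadrature (compiled kernel, analytic score) and
maximized by quasi-Newton iteration with observed-information standard
errors.  The package also implements the study workflow around the
model: descriptive tables with Pearson chi-square tests, univariate
multilevel screening at p < 0.20, Wald odds-ratio tables, and a
calibrated synthetic clustered-cohort generator standing in for the
unavailable raw cohort.

## Worked example

```r
library(jointbridge)

# a study-like cohort: 30 hospitals, 4415 mothers, outcomes drawn from
# the joint model with thresholds calibrated to the published prevalences
coh <- simulate_cohort(seed = 7)
prevalence(coh, gestational_age)
#> # A tibble: 3 × 3
#>   category     n percent
#>   <chr>    <int>   <dbl>
#> 1 preterm    143   3.24
#> 2 term      4255  96.4
#> 3 postterm    17   0.385

# univariate multilevel screening at p < 0.20
sc <- screen_predictors(coh, candidates = c("preeclampsia",
        "multiple_pregnancy", "art", "mother_age", "bmi", "infant_sex"))
attr(sc, "selected")
#> [1] "preeclampsia"       "multiple_pregnancy" "art"
#> [4] "mother_age"         "bmi"                "infant_sex"

# joint fit on the screened predictors
spec <- joint_spec(
  predictors1 = c("mother_age", "preeclampsia", "art", "multiple_pregnancy"),
  predictors2 = c("mother_age", "bmi", "infant_sex"))
fit <- fit_joint(coh, spec)
glance(fit)
#> # A tibble: 1 × 10
#>   logLik   AIC   BIC    df  nobs n_clusters converged  phi1  phi2   rho
#>    <dbl> <dbl> <dbl> <int> <int>      <int> <lgl>     <dbl> <dbl> <dbl>
#> 1   -973. 1989. 2123.    21  4415         30 TRUE      0.668 0.687 0.509

wald_intervals(fit) |> dplyr::filter(startsWith(contrast, "preterm"))
#> # A tibble: 4 × 10
#>   outcome         contrast        term               estimate std.error    or conf.low conf.high  p.value
#> 1 gestational_age preterm vs term mother_age            0.116    0.0214  1.12     1.08      1.17 6.13e- 8
#> 2 gestational_age preterm vs term preeclampsia          2.09     0.320   8.12     4.33     15.2  6.35e-11
#> 3 gestational_age preterm vs term art                   1.56     0.307   4.77     2.62      8.71 3.48e- 7
#> 4 gestational_age preterm vs term multiple_pregnancy    3.49     0.418  32.8     14.5      74.6  7.25e-17
```

The `or` column is the within-hospital odds ratio: in this replicate,
mothers with a multiple pregnancy have ~33 times the preterm-vs-term
odds of singleton mothers in the same hospital (the generating truth was
18.04 and lies inside the wide 95% interval — with 30 hospitals and
strong hospital heterogeneity, single-cohort estimates of rare-exposure
effects scatter this much).  `rho = 0.51` recovers the planted
hospital-level correlation 0.5 between the two outcomes' intercepts, and
`phi1`, `phi2` estimate the Bridge scales (planted 0.6).  `tidy(fit)`, `autoplot(fit)` and `render_or_table(fit)`
give the broom-style table, a forest plot, and the publication-layout
OR table; `run_pipeline(pipeline_config(...))` executes
descriptives → screening → joint fit → report on a cohort CSV and
writes the bundle (CSV/JSON, byte-identical across reruns with the same
seed).

The published descriptive surface is reproduced exactly from printed
counts:

```r
chisq_pearson(published_outcome_crosstab())
#> # A tibble: 1 × 3
#>   statistic    df   p.value
#>       <dbl> <int>     <dbl>
#> 1      940.     4 3.08e-202   # 940.308 at 3 decimals
```

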