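test_that("covariate marginals match the configured study summaries", {
  cfg <- cohort_config()
  covs <- simulate_covariates(cfg, seed = 101)
  expect_equal(nrow(covs), 4415)
  expect_equal(length(unique(covs$hospital)), 30)
  se_age <- sd(covs$mother_age) / sqrt(4415)
  expect_lt(abs(mean(covs$mother_age) - 29.18), 3 * se_age + 0.1)
  expect_true(all(covs$mother_age >= 15 & covs$mother_age <= 50))
  p_mult <- 62 / 4415
  se_mult <- sqrt(p_mult * (1 - p_mult) / 4415)
  expect_lt(abs(mean(covs$multiple_pregnancy == "Yes") - p_mult), 3 * se_mult)
  p_male <- 2239 / 4415
  se_male <- sqrt(p_male * (1 - p_male) / 4415)
  expect_lt(abs(mean(covs$infant_sex == "Male") - p_male), 3 * se_male)
  expect_identical(covs, simulate_covariates(cfg, seed = 101))
})

test_that("threshold calibration solves the marginal prevalence equations", {
  targets <- c(244, 22) / 4415
  om <- calibrate_thresholds(targets, phi = 0.6)
  # independent oracle: adaptive integration over the Bridge law
  marg <- vapply(1:2, function(cix) {
    integrate(function(u) {
      e1 <- exp(u + om[1]); e2 <- exp(u + om[2])
      p <- cbind(e1, e2) / (1 + e1 + e2)
      p[, cix] * dbridge(u, 0.6)
    }, -60, 60, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(marg, targets, tolerance = 1e-7)
  # with covariate offsets the iterative solution hits the target too
  withr::with_seed(5, off <- cbind(rnorm(5000, 0, 0.8), rnorm(5000, 0, 0.5)))
  om2 <- calibrate_thresholds(targets, phi = 0.6, offsets = off)
  gh <- jointbridge:::gauss_hermite_normal(41)
  u <- qbridge(pmin(pmax(pnorm(gh$nodes), 1e-15), 1 - 1e-15), 0.6)
  acc <- c(0, 0)
  for (k in seq_along(u)) {
    p <- category_probs(sweep(off, 2, om2, `+`), u = u[k])
    acc <- acc + gh$weights[k] * colMeans(p)[1:2]
  }
  expect_equal(unname(acc), targets, tolerance = 2e-4)
})

test_that("intercept-only outcomes hit the published prevalences", {
  # many clusters so the between-hospital variability averages out; the
  # standard error is taken from the observed between-cluster spread
  tr <- xtruth(rare_omega(), rare_theta(), rho = 0.5)
  coh <- sim_xcohort(400, 12, tr, seed = 301)
  for (case in list(list(col = "gestational_age", cat = "preterm", p = 244 / 4415),
                    list(col = "birth_weight", cat = "LBW", p = 213 / 4415),
                    list(col = "birth_weight", cat = "macrosomia", p = 124 / 4415))) {
    hit <- coh[[case$col]] == case$cat
    rates <- tapply(hit, coh$hospital, mean)
    se <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(hit) - case$p), 3 * se)
  }
})

test_that("planted effects drive the outcomes in the stated direction", {
  tr <- xtruth(rare_omega(), rare_theta(), a_pre = log(18), rho = 0.5)
  coh <- sim_xcohort(150, 30, tr, seed = 11)
  rate <- tapply(coh$gestational_age == "preterm", coh$x, mean)
  expect_gt(rate[["1"]], 4 * rate[["0"]])
})

test_that("copula correlation induces cluster-level outcome association", {
  rates <- lapply(c(0, 0.9), function(r) {
    tr <- xtruth(c(-2, -3), c(-2, -3), rho = r)
    coh <- sim_xcohort(200, 40, tr, seed = 55)
    tibble::tibble(
      pre = tapply(coh$gestational_age == "preterm", coh$hospital, mean),
      lbw = tapply(coh$birth_weight == "LBW", coh$hospital, mean))
  })
  expect_gt(cor(rates[[2]]$pre, rates[[2]]$lbw),
            cor(rates[[1]]$pre, rates[[1]]$lbw) + 0.3)
})

test_that("the default synthetic cohort is study-like and reproducible", {
  coh <- simulate_cohort(seed = 73)
  expect_equal(nrow(coh), 4415)
  expect_false(anyNA(coh))
  expect_true(all(table(coh$hospital) >= 1))
  pv <- prevalence(coh, gestational_age)
  expect_gt(pv$percent[pv$category == "preterm"], 3)
  expect_lt(pv$percent[pv$category == "preterm"], 8)
  expect_identical(coh, simulate_cohort(seed = 73))
})

test_that("cohort CSV round-trips through the pipeline dialect", {
  coh <- head(simulate_cohort(seed = 1), 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path, seed = 1)
  expect_match(readLines(path, n = 1), "seed: 1")
  back <- read_cohort(path)
  expect_equal(nrow(back), 50)
  expect_equal(as.character(back$gestational_age),
               as.character(coh$gestational_age))
})
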