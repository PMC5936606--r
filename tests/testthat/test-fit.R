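test_that("Wald odds-ratio arithmetic matches direct computation", {
  fit <- fabricate_fit(b1_pre = 0, b1_post = log(2), se1_pre = 0.1,
                       se1_post = 0.2, b2_lbw = 0.5, b2_mac = -0.3,
                       se2_lbw = 0.25, se2_mac = 0.15)
  w <- wald_intervals(fit)
  r0 <- w[w$contrast == "preterm vs term", ]
  expect_equal(r0$or, 1)
  expect_equal(r0$conf.low, exp(-1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(r0$conf.high, exp(1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(round(c(r0$conf.low, r0$conf.high), 3), c(0.822, 1.217))
  expect_equal(r0$p.value, 1)
  r1 <- w[w$contrast == "postterm vs term", ]
  expect_equal(r1$or, 2, tolerance = 1e-9)
  expect_equal(round(c(r1$conf.low, r1$conf.high), 3), c(1.351, 2.960))
})

test_that("confidence intervals exclude 1 exactly when p < 0.05 (Wald duality)", {
  fit <- fabricate_fit(b1_pre = 0.3, b1_post = -0.8, se1_pre = 0.18,
                       se1_post = 0.3, b2_lbw = 0.05, b2_mac = 0.6,
                       se2_lbw = 0.4, se2_mac = 0.22)
  w <- wald_intervals(fit, level = 0.95)
  excl <- w$conf.low > 1 | w$conf.high < 1
  expect_equal(excl, w$p.value < 0.05)
})

test_that("tidy and glance expose the fit in broom conventions", {
  fit <- fabricate_fit(0.2, 0.1, 0.1, 0.1, 0.2, 0.1, 0.1, 0.1)
  td <- tidy(fit)
  expect_true(all(c("outcome", "contrast", "term", "estimate", "std.error",
                    "p.value", "conf.low", "conf.high") %in% names(td)))
  expect_setequal(td$term[td$component == "dispersion"],
                  c("phi1", "phi2", "rho"))
  td_or <- tidy(fit, exponentiate = TRUE, component = "fixed")
  expect_equal(td_or$estimate, exp(td$estimate[td$component == "fixed"]))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df, 11)
  expect_equal(gl$AIC, -2 * fit$loglik + 22)
  # dispersion CIs are endpoint transforms staying inside the domain
  disp <- tidy(fit, component = "dispersion")
  expect_true(all(disp$conf.low > 0 & disp$conf.high < 1 |
                    disp$term == "rho"))
})

test_that("the joint fit recovers a planted effect within its interval", {
  tr <- xtruth(c(-1.6, -2.8), c(-2.2, -1.6), a_pre = log(3), b_mac = 0.5,
               rho = 0.5)
  coh <- sim_xcohort(30, 40, tr, seed = 17)
  fit <- fit_joint(coh, tr$spec, jb_control(n_starts = 1))
  expect_true(fit$converged)
  expect_true(fit$vcov_ok)
  td <- tidy(fit, component = "fixed")
  row <- td[td$term == "x" & grepl("^preterm", td$contrast), ]
  expect_lt(abs(row$estimate - log(3)), 3 * row$std.error)
  # covariance is positive definite at the optimum
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("replicate fits recover every generating parameter within 0.1", {
  spec <- joint_spec(predictors1 = "x", predictors2 = "x")
  truth <- structure(list(
    spec = spec,
    params = jb_params(c(-1.6, -2.4), matrix(c(log(3), 0.4), 1, 2),
                       c(-1.9, -1.3), matrix(c(0, -0.5), 1, 2),
                       0.6, 0.6, 0.5)), class = "jb_truth")
  res <- t(vapply(1:20, function(r) withr::with_seed(8000 + r, {
    covs <- tibble::tibble(
      hospital = factor(rep(sprintf("H%02d", 1:40), each = 80)),
      x = rbinom(3200, 1, 0.5))
    fit <- fit_joint(simulate_outcomes(covs, truth), spec,
                     jb_control(n_starts = 1))
    td <- tidy(fit, component = "fixed")
    c(td$estimate[td$term == "x"], fit$params$phi1, fit$params$phi2,
      fit$params$rho)
  }), numeric(7)))
  means <- colMeans(res)
  target <- c(log(3), 0.4, 0, -0.5, 0.6, 0.6, 0.5)
  expect_true(all(abs(means - target) < 0.1))
})

test_that("independence fit equals the stacked univariate fits", {
  tr <- xtruth(c(-1.5, -2.5), c(-2, -1.2), a_pre = 1, b_lbw = 0.5, rho = 0)
  coh <- sim_xcohort(20, 80, tr, seed = 2)
  jf <- fit_joint(coh, tr$spec, jb_control(n_starts = 1, fix_rho = 0))
  u1 <- fit_univariate(coh, "outcome1", "x", tr$spec, jb_control(n_starts = 1))
  u2 <- fit_univariate(coh, "outcome2", "x", tr$spec, jb_control(n_starts = 1))
  expect_true(jf$converged && u1$converged && u2$converged)
  expect_equal(jf$loglik, u1$loglik + u2$loglik, tolerance = 1e-4)
})

test_that("population-averaged slopes are attenuated by phi (the Bridge rationale)", {
  # binary logistic analogue: cluster-ignoring ML recovers phi * slope
  phi <- 0.6; b <- 1.2
  withr::with_seed(123, {
    ncl <- 400; size <- 30
    u <- rbridge(ncl, phi)
    x <- rnorm(ncl * size)
    eta <- u[rep(seq_len(ncl), each = size)] + 0.3 + b * x
    y <- rbinom(ncl * size, 1, plogis(eta))
  })
  marg <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(marg)["x"]), phi * b, tolerance = 0.08)
})

test_that("fits are deterministic given data and options", {
  tr <- xtruth(c(-1.2, -2.2), c(-1.5, -1.8), a_pre = 0.8)
  coh <- sim_xcohort(6, 30, tr, seed = 8)
  f1 <- fit_joint(coh, tr$spec, jb_control(n_starts = 2))
  f2 <- fit_joint(coh, tr$spec, jb_control(n_starts = 2))
  expect_identical(f1$psi, f2$psi)
  expect_identical(f1$loglik, f2$loglik)
})
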