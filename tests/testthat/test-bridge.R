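test_that("density has the closed-form value at 0, symmetry, and unit mass", {
  expect_equal(dbridge(0, 0.5), 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(dbridge(3, 0.5), dbridge(-3, 0.5))
  for (phi in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    mass <- integrate(dbridge, -Inf, Inf, phi = phi, rel.tol = 1e-12)$value
    expect_lt(abs(mass - 1), 1e-8)
  }
  expect_error(dbridge(0, 1.2), "phi")
  expect_error(dbridge(0, 0), "phi")
})

test_that("quantile function is the inverse of the integrated density", {
  expect_equal(qbridge(0.5, 0.3), 0)
  expect_equal(qbridge(0.8, 0.4), -qbridge(0.2, 0.4))
  # F(F^-1(p)) = p against the integration oracle
  for (p in c(0.05, 0.3, 0.9)) {
    v <- qbridge(p, 0.4)
    expect_lt(abs(bridge_cdf_num(v, 0.4) - p), 1e-6)
  }
  # strictly increasing
  ps <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(qbridge(ps, 0.6)) > 0))
  expect_error(qbridge(0, 0.5), "p")
  expect_error(qbridge(1.5, 0.5), "p")
})

test_that("pbridge inverts qbridge and matches the integration oracle", {
  ps <- c(0.01, 0.2, 0.5, 0.77, 0.999)
  qs <- qbridge(ps, 0.35)
  expect_equal(pbridge(qs, 0.35), ps, tolerance = 1e-9)
  expect_lt(max(abs(pbridge(c(-2, 0, 1.5), 0.6) -
                      bridge_cdf_num(c(-2, 0, 1.5), 0.6))), 1e-8)
})

test_that("quantile derivative is the reciprocal density (icdf/pdf consistency)", {
  h <- 1e-6
  for (phi in c(0.3, 0.6, 0.85)) {
    for (p in c(0.1, 0.45, 0.8)) {
      dq <- (qbridge(p + h, phi) - qbridge(p - h, phi)) / (2 * h)
      expect_lt(abs(dq - 1 / dbridge(qbridge(p, phi), phi)), 1e-5 * dq)
    }
  }
})

test_that("variance closed form matches the second-moment integral and limits", {
  for (phi in c(0.3, 0.5, 0.8)) {
    m2 <- integrate(function(u) u^2 * dbridge(u, phi), -Inf, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(bridge_variance(phi), m2, tolerance = 1e-6)
  }
  expect_equal(bridge_variance(0.5), pi^2, tolerance = 1e-12)
  expect_lt(bridge_variance(0.99), 0.07)
  expect_lt(bridge_variance(0.9999), 1e-3)  # degenerates to a point mass
})

test_that("sampler agrees with the analytic moments and is seed-deterministic", {
  n <- 1e5
  u <- rbridge(n, 0.6, seed = 42)
  expect_identical(u, rbridge(n, 0.6, seed = 42))
  se_mean <- sqrt(bridge_variance(0.6) / n)
  expect_lt(abs(mean(u)), 3 * se_mean)
  expect_lt(abs(var(u) / bridge_variance(0.6) - 1), 0.05)
  ks <- suppressWarnings(stats::ks.test(u, function(q) pbridge(q, 0.6)))
  expect_gt(ks$p.value, 0.01)
  expect_error(rbridge(0, 0.5), "n")
})

test_that("bivariate sampler preserves margins and orders correlation by rho", {
  n <- 1e5
  ind <- rbridge2(n, 0.6, 0.4, rho = 0, seed = 1)
  expect_lt(abs(cor(ind$u1, ind$u2)), 3 / sqrt(n))
  lo <- rbridge2(n, 0.6, 0.6, rho = 0.2, seed = 2)
  hi <- rbridge2(n, 0.6, 0.6, rho = 0.8, seed = 2)
  expect_gt(cor(hi$u1, hi$u2, method = "spearman"),
            cor(lo$u1, lo$u2, method = "spearman"))
  # margins: KS against the numeric CDF at alpha = 0.01
  ks1 <- suppressWarnings(stats::ks.test(hi$u1, function(q) pbridge(q, 0.6)))
  ks2 <- suppressWarnings(stats::ks.test(hi$u2, function(q) pbridge(q, 0.6)))
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
  expect_error(rbridge2(10, 0.6, 0.6, rho = 1), "rho")
})

test_that("marginalizing the logit over a Bridge intercept attenuates by phi", {
  expect_equal(bridge_marginal_prob(0, 0.7), 0.5)
  for (case in list(c(1, 0.5), c(-2, 0.7))) {
    eta <- case[1]; phi <- case[2]
    num <- integrate(function(u) plogis(u + eta) * dbridge(u, phi),
                     -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(num - bridge_marginal_prob(eta, phi)), 1e-6)
  }
})
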