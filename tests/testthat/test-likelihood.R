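test_that("category probabilities follow the baseline-category softmax", {
  expect_equal(unname(category_probs(c(0, 0))), rep(1 / 3, 3))
  p <- category_probs(c(log(2), 0))
  expect_equal(unname(p), c(0.5, 0.25, 0.25))
  expect_lt(abs(category_probs(c(-50, -50))[["ref"]] - 1), 1e-20)
  # rows sum to one; extreme predictors never give NaN
  m <- category_probs(matrix(c(700, -700, 30, -30), 2), u = c(5, -5))
  expect_false(anyNA(m))
  expect_equal(rowSums(m), c(1, 1))
})

test_that("a degenerate random intercept gives uniform-category log-likelihood", {
  spec <- joint_spec(predictors1 = "x", predictors2 = "x")
  one <- tibble::tibble(
    hospital = "A", x = 0,
    gestational_age = factor("term", levels = spec$categories1),
    birth_weight = factor("normal", levels = spec$categories2))
  pp <- jb_params(c(0, 0), matrix(0, 1, 2), c(0, 0), matrix(0, 1, 2),
                  0.999, 0.999, 0)
  expect_equal(cluster_loglik(one, pp, spec = spec), 2 * log(1 / 3),
               tolerance = 1e-3)
  expect_error(cluster_loglik(one[0, ], pp, spec = spec), "[Ee]mpty")
})

test_that("cluster likelihood matches Monte-Carlo copula integration", {
  truth <- xtruth(c(-1.5, -2.5), c(-2, -1.2), a_pre = 1, b_mac = 0.5,
                  rho = 0.6)
  pp <- truth$params
  withr::with_seed(99, {
    nmc <- 2e5
    uu <- rbridge2(nmc, pp$phi1, pp$phi2, pp$rho)
    for (k in 1:5) {
      size <- sample(3:8, 1)
      coh <- sim_xcohort(1, size, truth, seed = 100 + k)
      jbd <- build_design(coh, truth$spec)
      e1 <- sweep(jbd$X1 %*% pp$alpha, 2, pp$omega, `+`)
      e2 <- sweep(jbd$X2 %*% pp$beta, 2, pp$theta, `+`)
      lik <- rep(1, nmc)
      for (r in seq_len(size)) {
        p1 <- category_probs(e1[r, , drop = FALSE][rep(1, nmc), ], u = uu$u1)
        p2 <- category_probs(e2[r, , drop = FALSE][rep(1, nmc), ], u = uu$u2)
        pick <- function(p, y) if (y == 0) p[, 3] else p[, y]
        lik <- lik * pick(p1, jbd$y1[r]) * pick(p2, jbd$y2[r])
      }
      mc <- mean(lik)
      se_log <- sd(lik) / sqrt(nmc) / mc
      ll <- cluster_loglik(jbd, pp)
      expect_lt(abs(ll - log(mc)), 3 * se_log)
    }
  })
})

test_that("at rho = 0 the joint likelihood factorizes over outcomes exactly", {
  truth <- xtruth(c(-1.5, -2.5), c(-2, -1.2), a_pre = 1, rho = 0)
  coh <- sim_xcohort(6, 20, truth, seed = 5)
  jbd <- build_design(coh, truth$spec)
  pp <- truth$params
  ctrl <- jb_control(nodes = 9)
  llj <- as.numeric(total_loglik(jbd, pp, ctrl))
  u1 <- jointbridge:::engine_uni(jbd$cluster, jbd$y1, jbd$X1, pp$omega,
                                 pp$alpha, pp$phi1, ctrl)$loglik
  u2 <- jointbridge:::engine_uni(jbd$cluster, jbd$y2, jbd$X2, pp$theta,
                                 pp$beta, pp$phi2, ctrl)$loglik
  expect_lt(abs(llj - (u1 + u2)), 1e-8)
})

test_that("total log-likelihood is additive over clusters", {
  truth <- xtruth(c(-1.5, -2.5), c(-2, -1.2))
  coh <- sim_xcohort(4, 15, truth, seed = 21)
  pp <- truth$params
  ll1 <- as.numeric(total_loglik(coh, pp, spec = truth$spec))
  dup <- dplyr::mutate(coh, hospital = factor(paste0(.data$hospital, "bis")))
  both <- dplyr::bind_rows(coh, dup)
  expect_equal(as.numeric(total_loglik(both, pp, spec = truth$spec)),
               2 * ll1, tolerance = 1e-10)
  one <- dplyr::filter(coh, .data$hospital == "H001")
  expect_equal(cluster_loglik(one, pp, spec = truth$spec),
               attr(total_loglik(coh, pp, spec = truth$spec),
                    "by_cluster")[1])
})

test_that("adaptive quadrature is converged in the node count", {
  # moderate category prevalences: 15- and 21-node rules agree to 1e-6
  # per observation; the rare-category regime of the perinatal study is
  # harder and reaches that bound between 21 and 27 nodes
  mod <- xtruth(c(-1.5, -2.2), c(-1.8, -1.2), a_pre = 1, b_lbw = 0.5,
                rho = 0.4)
  coh <- sim_xcohort(10, 50, mod, seed = 13)
  jbd <- build_design(coh, mod$spec)
  ll <- function(m, pp) as.numeric(total_loglik(jbd, pp, jb_control(nodes = m)))
  expect_lt(abs(ll(15, mod$params) - ll(21, mod$params)) / 500, 1e-6)

  rare <- xtruth(rare_omega(), rare_theta(), a_pre = 1, rho = 0.4)
  coh2 <- sim_xcohort(10, 50, rare, seed = 13)
  jbd2 <- build_design(coh2, rare$spec)
  ll2 <- function(m) as.numeric(total_loglik(jbd2, rare$params,
                                             jb_control(nodes = m)))
  expect_lt(abs(ll2(21) - ll2(27)) / 500, 1e-6)
  # the fitting default stays within ~1e-4 per observation even there
  expect_lt(abs(ll2(7) - ll2(27)) / 500, 1e-4)
})

test_that("swapping the outcomes (with their parameters) leaves the likelihood unchanged", {
  tr <- xtruth(c(-1.5, -2.2), c(-1.8, -1.2), a_pre = 1, b_mac = -0.4,
               phi1 = 0.55, phi2 = 0.75, rho = 0.4)
  coh <- sim_xcohort(8, 40, tr, seed = 31)
  jbd <- build_design(coh, tr$spec)
  swapped <- jbd
  swapped$y1 <- jbd$y2; swapped$y2 <- jbd$y1
  swapped$X1 <- jbd$X2; swapped$X2 <- jbd$X1
  pp <- tr$params
  pps <- jb_params(pp$theta, pp$beta, pp$omega, pp$alpha,
                   pp$phi2, pp$phi1, pp$rho)
  ctrl <- jb_control(nodes = 15)
  expect_equal(as.numeric(total_loglik(jbd, pp, ctrl)),
               as.numeric(total_loglik(swapped, pps, ctrl)),
               tolerance = 1e-9)
})

test_that("analytic score equals the finite-difference gradient", {
  tr <- xtruth(c(-1.5, -2.5), c(-2, -1.2), a_pre = 1, b_lbw = 0.4, rho = 0.5)
  coh <- sim_xcohort(6, 25, tr, seed = 3)
  jbd <- build_design(coh, tr$spec)
  psi <- jointbridge:::par_pack(tr$params) + 0.05
  for (adaptive in c(FALSE, TRUE)) {
    ctrl <- jb_control(nodes = 9, adaptive = adaptive)
    obj <- jointbridge:::make_objective(jbd, ctrl)
    o <- if (adaptive) obj$with_adapt(obj$adapt_at(psi)) else obj
    g <- o$gr(psi)
    gfd <- vapply(seq_along(psi), function(i) {
      h <- 1e-6 * (1 + abs(psi[i]))
      up <- psi; up[i] <- up[i] + h
      dn <- psi; dn[i] <- dn[i] - h
      (o$fn(up) - o$fn(dn)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gfd)), 1e-5)
  }
})

test_that("moving a slope away from its generating value lowers the likelihood", {
  tr <- xtruth(c(-1.5, -2.5), c(-2, -1.2), a_pre = 1, rho = 0.4)
  coh <- sim_xcohort(40, 60, tr, seed = 77)
  jbd <- build_design(coh, tr$spec)
  ll_at <- function(a) {
    pp <- tr$params; pp$alpha[1, 1] <- a
    as.numeric(total_loglik(jbd, pp))
  }
  expect_gt(ll_at(1), ll_at(2))
  expect_gt(ll_at(1), ll_at(0))
})
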