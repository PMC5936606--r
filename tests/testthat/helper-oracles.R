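# Independent numerical oracles and small fixture builders.

# Bridge CDF by adaptive integration of the density (independent of the
# closed-form quantile that pbridge inverts).
bridge_cdf_num <- function(q, phi) {
  vapply(q, function(v)
    integrate(dbridge, -Inf, v, phi = phi, rel.tol = 1e-12)$value,
    numeric(1))
}

# a one-predictor two-outcome truth with given thresholds/slopes
xtruth <- function(omega, theta, a_pre = 0, a_post = 0, b_lbw = 0,
                   b_mac = 0, phi1 = 0.6, phi2 = 0.6, rho = 0.5) {
  spec <- joint_spec(predictors1 = "x", predictors2 = "x")
  structure(list(
    spec = spec,
    params = jb_params(omega, matrix(c(a_pre, a_post), 1, 2),
                       theta, matrix(c(b_lbw, b_mac), 1, 2),
                       phi1, phi2, rho)),
    class = "jb_truth")
}

# clustered cohort with one binary predictor
sim_xcohort <- function(n_clusters, size, truth, seed, p_x = 0.5) {
  withr::with_seed(seed, {
    covs <- tibble::tibble(
      hospital = factor(rep(sprintf("H%03d", seq_len(n_clusters)),
                            each = size)),
      x = stats::rbinom(n_clusters * size, 1, p_x))
    simulate_outcomes(covs, truth)
  })
}

# paper-like rare-category thresholds (marginal prevalences of the study)
rare_omega <- function(phi = 0.6) calibrate_thresholds(c(244, 22) / 4415, phi)
rare_theta <- function(phi = 0.6) calibrate_thresholds(c(213, 124) / 4415, phi)

# hand-built converged joint fit for reporting-layer tests: one binary
# predictor per sub-model, all standard errors supplied directly
fabricate_fit <- function(b1_pre, b1_post, se1_pre, se1_post,
                          b2_lbw, b2_mac, se2_lbw, se2_mac) {
  spec <- joint_spec(predictors1 = "x", predictors2 = "x",
                     references = list(x = "No"))
  psi <- c(-3, -5, b1_pre, b1_post, -3.5, -4, b2_lbw, b2_mac,
           qlogis(0.6), qlogis(0.6), atanh(0.3))
  se <- c(0.2, 0.3, se1_pre, se1_post, 0.2, 0.3, se2_lbw, se2_mac,
          0.4, 0.4, 0.3)
  structure(
    list(type = "joint",
         params = jb_params(psi[1:2], matrix(psi[3:4], 1), psi[5:6],
                            matrix(psi[7:8], 1), 0.6, 0.6, 0.3),
         psi = psi, vcov = diag(se^2), vcov_ok = TRUE,
         loglik = -1000, converged = TRUE,
         diagnostics = list(grad_norm = 1e-6, optim_convergence = 0L,
                            n_starts = 1L, adapt_rounds = 1L,
                            counts = c(1L, 1L)),
         n_obs = 1000L, n_clusters = 10L,
         spec = spec, terms1 = "x", terms2 = "x",
         control = jb_control()),
    class = "jb_fit")
}
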