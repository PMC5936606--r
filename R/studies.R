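#' Wald coverage (parameter recovery) study
#'
#' Because the original cohort is unavailable, the fitted odds ratios
#' cannot be reproduced; what can be verified is that the estimator
#' recovers known truth at the study's scale.  Each replicate simulates a
#' clustered cohort from the joint model with one balanced binary
#' predictor whose preterm log-odds slope is `effect` (all other slopes
#' zero), thresholds calibrated to the published marginal prevalences,
#' and Bridge/copula parameters (`phi`, `rho`); the joint model is then
#' refitted and the 95 percent Wald interval for the planted slope is
#' checked against the truth.
#'
#' @param n_reps Number of replicates.
#' @param n_clusters,cluster_size Cohort dimensions per replicate.
#' @param phi Bridge scale used for both outcomes.
#' @param rho Copula correlation.
#' @param effect Planted preterm log-odds ratio of the binary predictor.
#' @param seed Seed governing all replicates.
#' @param control Fitting controls (single-start by default: with one
#'   predictor the likelihood is well behaved and the study runs 100+
#'   fits).
#' @return A tibble with one row per replicate: `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `covered`, `converged`.
#' @export
wald_coverage_study <- function(n_reps = 100, n_clusters = 50,
                                cluster_size = 100, phi = 0.6, rho = 0.5,
                                effect = log(4), seed = 1,
                                control = jb_control(n_starts = 1)) {
  spec <- joint_spec(predictors1 = "x", predictors2 = "x")
  alpha <- matrix(c(effect, 0), 1, 2)
  beta <- matrix(0, 1, 2)
  # balanced binary predictor: offset distribution known exactly
  off1 <- rbind(c(0, 0), c(effect, 0))
  omega <- calibrate_thresholds(c(244, 22) / 4415, phi, offsets = off1)
  theta <- calibrate_thresholds(c(213, 124) / 4415, phi)
  truth <- structure(
    list(spec = spec,
         params = jb_params(omega, alpha, theta, beta, phi, phi, rho)),
    class = "jb_truth")

  n <- n_clusters * cluster_size
  with_seed_(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      covs <- tibble::tibble(
        hospital = factor(rep(sprintf("H%03d", seq_len(n_clusters)),
                              each = cluster_size)),
        x = rbinom(n, 1, 0.5))
      coh <- simulate_outcomes(covs, truth)
      fit <- tryCatch(fit_joint(coh, spec, control), error = function(e) NULL)
      if (is.null(fit))
        return(tibble::tibble(rep = r, estimate = NA_real_,
                              std.error = NA_real_, conf.low = NA_real_,
                              conf.high = NA_real_, covered = NA,
                              converged = FALSE,
                              alpha_postterm = NA_real_,
                              beta_lbw = NA_real_, beta_macrosomia = NA_real_,
                              phi1 = NA_real_, phi2 = NA_real_,
                              rho = NA_real_))
      td <- tidy.jb_fit(fit, component = "fixed")
      row <- dplyr::filter(td, .data$term == "x",
                           .data$outcome == spec$outcome1,
                           grepl("^preterm", .data$contrast))
      slope <- function(oc, pre) {
        r2 <- dplyr::filter(td, .data$term == "x", .data$outcome == oc,
                            startsWith(.data$contrast, pre))
        r2$estimate
      }
      tibble::tibble(rep = r, estimate = row$estimate,
                     std.error = row$std.error,
                     conf.low = row$conf.low, conf.high = row$conf.high,
                     covered = row$conf.low <= effect & effect <= row$conf.high,
                     converged = fit$converged,
                     alpha_postterm = slope(spec$outcome1, "postterm"),
                     beta_lbw = slope(spec$outcome2, "LBW"),
                     beta_macrosomia = slope(spec$outcome2, "macrosomia"),
                     phi1 = fit$params$phi1, phi2 = fit$params$phi2,
                     rho = fit$params$rho)
    })
  })
}

#' Screening type-I calibration study
#'
#' Simulates cohorts with no predictor effects, adds a pure-noise
#' standard-normal predictor, and records the univariate screening
#' likelihood-ratio p-value for one outcome.  Under the null the
#' selection rate at threshold t should be close to t.
#'
#' @param n_sims Number of simulated cohorts.
#' @param n_clusters,n_mothers Cohort dimensions.
#' @param outcome Which outcome's screening test to calibrate
#'   (`"outcome1"` or `"outcome2"`).
#' @param phi,rho Generating intercept parameters.
#' @param threshold Screening threshold (default 0.20).
#' @param seed Seed governing all simulations.
#' @param control Fitting controls.
#' @return A tibble with one row per simulation: `p.value`, `selected`.
#' @export
screening_null_study <- function(n_sims = 200, n_clusters = 30,
                                 n_mothers = 4415, outcome = "outcome2",
                                 phi = 0.6, rho = 0.5, threshold = 0.20,
                                 seed = 1,
                                 control = jb_control(n_starts = 1)) {
  spec <- joint_spec(predictors1 = character(), predictors2 = character())
  omega <- calibrate_thresholds(c(244, 22) / 4415, phi)
  theta <- calibrate_thresholds(c(213, 124) / 4415, phi)
  truth <- structure(
    list(spec = spec,
         params = jb_params(omega, NULL, theta, NULL, phi, phi, rho)),
    class = "jb_truth")
  cfg <- cohort_config(n_clusters = n_clusters, n_mothers = n_mothers)

  with_seed_(seed, {
    purrr::map_dfr(seq_len(n_sims), function(s) {
      w <- rgamma(n_clusters, shape = cfg$cluster_balance,
                  rate = cfg$cluster_balance)
      sizes <- as.vector(rmultinom(1, n_mothers, w / sum(w)))
      covs <- tibble::tibble(
        hospital = factor(rep(sprintf("H%02d", seq_len(n_clusters)), sizes)),
        x = rnorm(n_mothers))
      coh <- simulate_outcomes(covs, truth)
      null <- fit_univariate(coh, outcome = outcome, predictor = NULL,
                             spec = spec, control = control)
      alt <- fit_univariate(coh, outcome = outcome, predictor = "x",
                            spec = spec, control = control)
      lr <- max(2 * (alt$loglik - null$loglik), 0)
      p <- pchisq(lr, df = 2, lower.tail = FALSE)
      tibble::tibble(sim = s, statistic = lr, p.value = p,
                     selected = p < threshold)
    })
  })
}
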