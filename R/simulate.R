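#' Configuration of a synthetic clustered cohort
#'
#' Describes the stand-in cohort the generator draws: mothers nested in
#' maternity hospitals, covariate marginals echoing the published
#' descriptive tables, and outcomes simulated forward from the joint
#' Bridge random-intercept model.  The number of hospitals in the original
#' study is unreported; the default of 30 clusters (university-supervised
#' centres, plausibly tens) with unequal sizes totalling 4415 mothers is
#' an explicit assumption surfaced here.
#'
#' @param n_clusters Number of hospitals (default 30).
#' @param n_mothers Total cohort size (default 4415).
#' @param cluster_balance Gamma shape controlling how unequal hospital
#'   sizes are (larger = more balanced; default 5).
#' @param covariates Per-covariate distribution list; see
#'   [default_covariate_spec()].
#' @param truth A `jb_truth` (spec + generating parameters), or `NULL` for
#'   [default_truth()] evaluated lazily.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_clusters = 30, n_mothers = 4415,
                          cluster_balance = 5,
                          covariates = default_covariate_spec(),
                          truth = NULL, seed = 1L) {
  stopifnot(n_clusters >= 1, n_mothers >= n_clusters, cluster_balance > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 n_mothers = as.integer(n_mothers),
                 cluster_balance = cluster_balance,
                 covariates = covariates, truth = truth,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default covariate marginals of the synthetic cohort
#'
#' Independent draws whose marginals match the published cohort summaries:
#' truncated normals for the continuous maternal measurements and
#' Bernoulli draws (at the table prevalences) for the binary factors, with
#' the study's label conventions (reference label first).
#'
#' @return A named list of distribution descriptions.
#' @export
default_covariate_spec <- function() {
  tn <- function(mean, sd, lower, upper)
    list(dist = "truncnorm", mean = mean, sd = sd, lower = lower, upper = upper)
  bn <- function(p, labels) list(dist = "binary", p = p, labels = labels)
  list(
    mother_age         = tn(29.18, 5.35, 15, 50),
    father_age         = tn(33.50, 5.75, 18, 65),
    ses                = list(dist = "normal", mean = 0, sd = 2),
    bmi                = tn(25.0, 5.0, 15, 45),
    parity             = bn(2255 / 4415, c("1", "2+")),
    mother_education   = bn(1446 / 4415, c("Undergraduate", "Graduate")),
    father_education   = bn(1415 / 4415, c("Undergraduate", "Graduate")),
    mother_occupation  = bn(540 / 4415, c("Housewife", "Employed")),
    pregnancy_type     = bn(852 / 4415, c("Wanted", "Unwanted")),
    abortion_history   = bn(852 / 4415, c("No", "Yes")),
    stillbirth_history = bn(77 / 4415, c("No", "Yes")),
    preeclampsia       = bn(235 / 4415, c("No", "Yes")),
    art                = bn(332 / 4415, c("No", "Yes")),
    multiple_pregnancy = bn(62 / 4415, c("No", "Yes")),
    infant_sex         = bn(2239 / 4415, c("Female", "Male"))
  )
}

#' Generating truth of the default synthetic cohort
#'
#' The parameter vector the default cohort is simulated from: slopes in
#' the directions of the published multivariable odds ratios (conditional
#' scale), Bridge scales `phi1 = phi2 = 0.6`, copula correlation
#' `rho = 0.5`, and thresholds calibrated so that the marginal category
#' prevalences match the published rates (preterm/term/postterm
#' 5.5/94.0/0.5 and LBW/normal/macrosomia 4.8/92.4/2.8 percent).  Four
#' planted effects whose published point estimates alone would give only
#' borderline univariate screening power (mother's age and assisted
#' reproduction on preterm; BMI and infant sex on macrosomia) are
#' strengthened so the screening stage has unambiguous signal to find;
#' see the methods vignette.
#'
#' Calibration solves the marginal prevalence equations numerically,
#' starting from the closed-form solution given by the Bridge
#' marginalization identity, against a large internally seeded covariate
#' sample; the result is memoised for the session.
#'
#' @return A list of class `jb_truth` with elements `spec` and `params`.
#' @export
default_truth <- function() {
  if (!is.null(the$default_truth)) return(the$default_truth)
  spec <- default_spec()
  # slopes on the conditional (within-hospital) log-odds scale
  alpha <- cbind(                       # gestational age: preterm, postterm
    preterm  = c(mother_age = 0.08, ses = -0.03, mother_education = 0.25,
                 preeclampsia = log(4.14), art = log(3.2),
                 multiple_pregnancy = log(18.04)),
    postterm = c(mother_age = log(0.92), ses = log(0.53),
                 mother_education = log(0.82), preeclampsia = 0, art = 0,
                 multiple_pregnancy = 0))
  beta <- cbind(                        # birth weight: LBW, macrosomia
    LBW        = c(mother_age = log(1.01), bmi = log(1.01),
                   mother_education = log(1.15),
                   stillbirth_history = log(2.17),
                   multiple_pregnancy = log(17.35),
                   preeclampsia = log(3.36), infant_sex = log(0.87)),
    macrosomia = c(mother_age = log(1.01), bmi = 0.09,
                   mother_education = log(1.10),
                   stillbirth_history = log(2.47),
                   multiple_pregnancy = log(0.72),
                   preeclampsia = log(1.4), infant_sex = log(2.0)))
  phi1 <- 0.6; phi2 <- 0.6; rho <- 0.5

  covs <- with_seed_(777,
    simulate_covariates(cohort_config(n_clusters = 2, n_mothers = 20000)))
  jbd <- build_design(covs, spec, require_outcomes = FALSE)
  omega <- calibrate_thresholds(c(244, 22) / 4415, phi1,
                                offsets = jbd$X1 %*% alpha)
  theta <- calibrate_thresholds(c(213, 124) / 4415, phi2,
                                offsets = jbd$X2 %*% beta)
  truth <- structure(
    list(spec = spec,
         params = jb_params(omega, alpha, theta, beta, phi1, phi2, rho)),
    class = "jb_truth")
  the$default_truth <- truth
  truth
}

#' Calibrate baseline-category thresholds to target prevalences
#'
#' Solves for thresholds \eqn{\omega_1, \omega_2} such that the marginal
#' (over covariates and the Bridge intercept) category probabilities match
#' `targets`.  The starting point is exact when all slopes are zero:
#' writing \eqn{\tau = p_1 + p_2} for the total non-reference probability,
#' the Bridge marginalization identity gives
#' \eqn{\log(e^{\omega_1} + e^{\omega_2}) = \mathrm{logit}(\tau)/\phi}, and
#' the within-cluster ratio \eqn{P_1/P_2 = e^{\omega_1 - \omega_2}} is
#' unchanged by marginalization, so
#' \eqn{\omega_c = \mathrm{logit}(\tau)/\phi + \log(p_c/\tau)}.  With
#' covariate offsets, a damped ratio-matching iteration refines this
#' start, averaging category probabilities over the offsets and a
#' Gauss-Hermite representation of the Bridge law.
#'
#' @param targets Length-2 vector of target marginal probabilities for the
#'   two non-reference categories.
#' @param phi Bridge scale of the outcome's random intercept.
#' @param offsets Optional `n x 2` matrix of per-subject linear-predictor
#'   contributions \eqn{x_j'\alpha_c} (NULL for intercept-only).
#' @param nodes Gauss-Hermite nodes for the intercept integral.
#' @param tol,max_iter Convergence controls on the log prevalence ratio.
#' @return Length-2 threshold vector.
#' @export
calibrate_thresholds <- function(targets, phi, offsets = NULL, nodes = 31,
                                 tol = 1e-10, max_iter = 200) {
  stopifnot(length(targets) == 2, all(targets > 0), sum(targets) < 1)
  check_phi(phi)
  tau <- sum(targets)
  om <- qlogis(tau) / phi + log(targets / tau)
  if (is.null(offsets)) return(unname(om))
  offsets <- as.matrix(offsets)
  stopifnot(ncol(offsets) == 2)
  gh <- gauss_hermite_normal(nodes)
  pz <- pmin(pmax(pnorm(gh$nodes), 1e-15), 1 - 1e-15)
  u <- qbridge(pz, phi)
  prev <- function(om) {
    acc <- c(0, 0)
    for (k in seq_along(u)) {
      p <- category_probs(sweep(offsets, 2, om, `+`), u = u[k])
      if (is.null(dim(p))) p <- matrix(p, 1)
      acc <- acc + gh$weights[k] * colMeans(p)[1:2]
    }
    acc
  }
  for (it in seq_len(max_iter)) {
    adj <- log(targets / prev(om))
    om <- om + adj
    if (max(abs(adj)) < tol) break
  }
  unname(om)
}

#' Draw the covariate table of a synthetic cohort
#'
#' Hospitals receive unequal shares of the cohort (Gamma-weighted
#' multinomial allocation); covariates are drawn independently from the
#' configured marginals.  Truncated normals use inverse-CDF sampling.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed (NULL uses the current RNG stream).
#' @return A tibble with `hospital` and one column per covariate.
#' @export
simulate_covariates <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed_(seed, {
    w <- rgamma(config$n_clusters, shape = config$cluster_balance,
                rate = config$cluster_balance)
    sizes <- as.vector(rmultinom(1, config$n_mothers, w / sum(w)))
    hosp <- factor(rep(sprintf("H%02d", seq_len(config$n_clusters)), sizes))
    n <- config$n_mothers
    cols <- lapply(config$covariates, function(cv) {
      switch(cv$dist,
        truncnorm = {
          plo <- pnorm(cv$lower, cv$mean, cv$sd)
          phi_ <- pnorm(cv$upper, cv$mean, cv$sd)
          qnorm(runif(n, plo, phi_), cv$mean, cv$sd)
        },
        normal = rnorm(n, cv$mean, cv$sd),
        binary = cv$labels[1 + rbinom(n, 1, cv$p)],
        abort(sprintf("Unknown covariate distribution '%s'.", cv$dist)))
    })
    tibble::tibble(hospital = hosp, !!!cols)
  })
}

#' Simulate the two outcomes from the joint model
#'
#' Per hospital a correlated Bridge intercept pair is drawn through the
#' Gaussian copula; per mother the conditional category probabilities of
#' both sub-models are evaluated and the outcome categories sampled.
#'
#' @param covariates A covariate table (as from [simulate_covariates()]).
#' @param truth A `jb_truth` (defaults to [default_truth()]).
#' @param seed Optional seed.
#' @return The covariate tibble with outcome columns appended.
#' @export
simulate_outcomes <- function(covariates, truth = default_truth(),
                              seed = NULL) {
  stopifnot(inherits(truth, "jb_truth"))
  spec <- truth$spec; pp <- truth$params
  jbd <- build_design(covariates, spec, require_outcomes = FALSE)
  if (nrow(jbd$data) != nrow(covariates))
    abort("Covariate table has missing values; complete data required for simulation.")
  stopifnot(nrow(pp$alpha) == ncol(jbd$X1), nrow(pp$beta) == ncol(jbd$X2))
  with_seed_(seed, {
    ncl <- length(unique(jbd$cluster))
    uu <- rbridge2(ncl, pp$phi1, pp$phi2, pp$rho)
    draw <- function(X, om, sl, u, categories, ref) {
      eta <- sweep(X %*% sl, 2, om, `+`)
      pr <- category_probs(eta, u = u)
      if (is.null(dim(pr))) pr <- matrix(pr, 1)
      r <- runif(nrow(pr))
      idx <- 1L + (r >= pr[, 1]) + (r >= pr[, 1] + pr[, 2])
      lab <- c(setdiff(categories, ref), ref)[idx]
      factor(lab, levels = categories)
    }
    y1 <- draw(jbd$X1, pp$omega, pp$alpha, uu$u1[jbd$cluster],
               spec$categories1, spec$ref1)
    y2 <- draw(jbd$X2, pp$theta, pp$beta, uu$u2[jbd$cluster],
               spec$categories2, spec$ref2)
    out <- jbd$data
    out[[spec$outcome1]] <- y1
    out[[spec$outcome2]] <- y2
    out
  })
}

#' One-call synthetic cohort
#'
#' Draws a complete study-like cohort -- hospitals, covariates and both
#' outcomes -- whose descriptive tables are qualitatively comparable to
#' the published ones.  Deterministic given the seed.
#'
#' @param seed Integer seed (defaults to the config's seed).
#' @param config A [cohort_config()].
#' @return A tibble of one row per mother.
#' @examples
#' coh <- simulate_cohort(seed = 42,
#'                        config = cohort_config(n_clusters = 8, n_mothers = 500))
#' prevalence(coh, gestational_age)
#' @export
simulate_cohort <- function(seed = NULL, config = cohort_config()) {
  truth <- config$truth %||% default_truth()
  with_seed_(seed %||% config$seed, {
    covs <- simulate_covariates(config)
    simulate_outcomes(covs, truth)
  })
}

#' Write / read a cohort CSV
#'
#' The CSV dialect the pipeline reads (comma-separated, header, UTF-8)
#' with the generating seed recorded in a `#`-comment header line.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @param seed Seed to record (optional).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  writeLines(sprintf("# jointbridge cohort%s",
                     if (is.null(seed)) "" else sprintf("; seed: %d", seed)),
             path)
  readr::write_csv(cohort, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
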