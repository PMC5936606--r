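#' Maximum-likelihood fit of the joint multilevel model
#'
#' Maximizes the marginal likelihood of the two-outcome baseline-category
#' model with correlated Bridge random intercepts by quasi-Newton (BFGS)
#' iteration on an unconstrained parametrization (`phi` via inverse-logit,
#' `rho` via tanh), using the compiled adaptive-quadrature kernel and its
#' analytic score.  Standard errors come from the observed information
#' (central-difference Jacobian of the score at the optimum).
#'
#' Starting values are deterministic: slopes 0, thresholds from the
#' marginal category frequencies divided by the starting scale, `phi = 0.7`
#' and `rho = 0`; additional jittered starts (see [jb_control()]) guard
#' against local optima while keeping the fit a pure function of data and
#' options.
#'
#' @param data A data frame or a `jb_data` from [build_design()].
#' @param spec A [joint_spec()] (ignored when `data` is already coded).
#' @param control A [jb_control()].
#' @return An object of class `jb_fit` with [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot]
#'   methods.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(seed = 1, config = cohort_config(n_clusters = 10,
#'                                                         n_mothers = 600))
#' fit <- fit_joint(coh, control = jb_control(n_starts = 1))
#' glance(fit)
#' }
#' @export
fit_joint <- function(data, spec = default_spec(), control = jb_control()) {
  jbd <- if (inherits(data, "jb_data")) data else build_design(data, spec)
  spec <- jbd$spec
  ncl <- length(unique(jbd$cluster))
  if (ncl < 2) abort("At least two clusters are required.")
  check_full_rank(jbd$X1, "sub-model 1")
  check_full_rank(jbd$X2, "sub-model 2")

  p1 <- ncol(jbd$X1); p2 <- ncol(jbd$X2)
  phi0 <- 0.7
  start <- jb_params(
    omega = start_thresholds(jbd$y1, phi0),
    alpha = matrix(0, p1, 2),
    theta = start_thresholds(jbd$y2, phi0),
    beta = matrix(0, p2, 2),
    phi1 = phi0, phi2 = phi0, rho = control$fix_rho %||% 0)
  psi0 <- par_pack(start)

  # optimize on internally standardized predictors (well-conditioned
  # Hessian); estimates and covariance are mapped back exactly below
  sd1 <- standardize_design(jbd$X1); sd2 <- standardize_design(jbd$X2)
  jbd_std <- jbd; jbd_std$X1 <- sd1$X; jbd_std$X2 <- sd2$X
  obj <- make_objective(jbd_std, control)
  res <- run_starts(obj, psi0, control)

  gr_frozen <- if (is.null(res$adapt)) obj$gr else obj$with_adapt(res$adapt)$gr
  M <- res$info %||% fd_score_jacobian(gr_frozen, res$psi)
  if (!is.null(control$fix_rho)) {
    # the pinned coordinate carries no information; invert the free block
    np <- length(res$psi)
    vc <- vcov_from_info(M[-np, -np, drop = FALSE])
    if (!is.null(vc$vcov)) {
      full <- matrix(0, np, np)
      full[-np, -np] <- vc$vcov
      vc$vcov <- full
    }
  } else {
    vc <- vcov_from_info(M)
  }
  A <- unstd_matrix_joint(sd1, sd2)
  res$psi <- as.numeric(A %*% res$psi)
  if (!is.null(vc$vcov)) {
    vc$vcov <- A %*% vc$vcov %*% t(A)
    if (!is.null(control$fix_rho)) {
      np <- length(res$psi)
      vc$vcov[np, ] <- NA_real_; vc$vcov[, np] <- NA_real_
    }
  }
  pp <- par_unpack(res$psi, p1, p2)
  out <- structure(
    list(type = "joint",
         params = pp, psi = res$psi,
         vcov = vc$vcov, vcov_ok = vc$ok,
         loglik = -res$value,
         converged = res$converged && vc$ok,
         diagnostics = c(res$diagnostics, list(info_clamped = vc$clamped)),
         n_obs = nrow(jbd$data), n_clusters = ncl,
         spec = spec,
         terms1 = colnames(jbd$X1), terms2 = colnames(jbd$X2),
         control = control),
    class = "jb_fit")
  if (!out$converged)
    warn("fit_joint: optimizer did not meet the convergence criteria; inspect `$diagnostics`.")
  out
}

#' Univariate multilevel baseline-category fit
#'
#' Fits a single-outcome nominal logistic model with one Bridge random
#' intercept and at most one predictor -- the screening stage's model.
#'
#' @param data A data frame.
#' @param outcome `"outcome1"` or `"outcome2"`, or the outcome column name.
#' @param predictor A single predictor column name, or `NULL` for an
#'   intercept-only model.
#' @inheritParams fit_joint
#' @return A `jb_fit` of type `"univariate"`.
#' @export
fit_univariate <- function(data, outcome = "outcome1", predictor = NULL,
                           spec = default_spec(), control = jb_control()) {
  which2 <- if (outcome %in% c("outcome1", spec$outcome1)) 1L
            else if (outcome %in% c("outcome2", spec$outcome2)) 2L
            else abort(sprintf("Unknown outcome '%s'.", outcome))
  ocol <- if (which2 == 1) spec$outcome1 else spec$outcome2
  cats <- if (which2 == 1) spec$categories1 else spec$categories2
  ref  <- if (which2 == 1) spec$ref1 else spec$ref2

  data <- tibble::as_tibble(data)
  for (nm in c(spec$cluster, ocol, predictor))
    if (!nm %in% names(data)) abort(sprintf("Missing column `%s`.", nm))

  y <- code_outcome(data[[ocol]], ocol, cats, ref)
  xv <- if (is.null(predictor)) NULL
        else code_predictor(data[[predictor]], predictor, spec$references)
  keep <- !is.na(y) & !is.na(data[[spec$cluster]])
  if (!is.null(xv)) keep <- keep & !is.na(xv)
  cl_raw <- data[[spec$cluster]][keep]
  ord <- order(match(cl_raw, unique(cl_raw)))
  cl <- as.integer(factor(cl_raw, levels = unique(cl_raw)))[ord]
  y <- y[keep][ord]
  X <- if (is.null(xv)) matrix(0, sum(keep), 0)
       else matrix(xv[keep][ord], ncol = 1,
                   dimnames = list(NULL, predictor))
  if (ncol(X) == 1) check_full_rank(X, "univariate model")
  ncl <- length(unique(cl))
  if (ncl < 2) abort("At least two clusters are required.")

  p <- ncol(X)
  phi0 <- 0.7
  psi0 <- c(start_thresholds(y, phi0), rep(0, 2 * p), qlogis(phi0))

  sdx <- standardize_design(X)
  obj <- make_uni_objective(cl, y, sdx$X, control)
  res <- run_starts(obj, psi0, control)
  gr_frozen <- if (is.null(res$adapt)) obj$gr else obj$with_adapt(res$adapt)$gr
  vc <- vcov_from_info(res$info %||% fd_score_jacobian(gr_frozen, res$psi))
  A <- unstd_matrix_block(sdx, extra = 1)
  res$psi <- as.numeric(A %*% res$psi)
  if (!is.null(vc$vcov)) vc$vcov <- A %*% vc$vcov %*% t(A)

  psi <- res$psi
  sl <- matrix(psi[2 + seq_len(2 * p)], ncol = 2,
               dimnames = list(colnames(X), NULL))
  out <- structure(
    list(type = "univariate", which = which2,
         params = list(omega = psi[1:2], alpha = sl,
                       phi = plogis(psi[2 + 2 * p + 1])),
         psi = psi, vcov = vc$vcov, vcov_ok = vc$ok,
         loglik = -res$value,
         converged = res$converged && vc$ok,
         diagnostics = c(res$diagnostics, list(info_clamped = vc$clamped)),
         n_obs = length(y), n_clusters = ncl,
         spec = spec, outcome = ocol,
         terms1 = colnames(X), terms2 = NULL,
         control = control),
    class = "jb_fit")
  out
}

# centre and scale predictor columns for optimization
#' @noRd
standardize_design <- function(X) {
  if (ncol(X) == 0)
    return(list(X = X, center = numeric(0), scale = numeric(0)))
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, m), 2, s, "/"), center = m, scale = s)
}

# linear map from the standardized-parametrization vector back to the
# original scale for one outcome block: thresholds (2) then the two
# category-specific slope sets (p each), followed by `extra` untouched
# parameters
#' @noRd
unstd_matrix_block <- function(sdx, extra) {
  p <- length(sdx$center)
  np <- 2 + 2 * p + extra
  A <- diag(np)
  for (cix in 1:2) {
    sl <- 2 + (cix - 1) * p + seq_len(p)
    for (j in seq_len(p)) {
      A[cix, sl[j]] <- -sdx$center[j] / sdx$scale[j]
      A[sl[j], sl[j]] <- 1 / sdx$scale[j]
    }
  }
  A
}

#' @noRd
unstd_matrix_joint <- function(sd1, sd2) {
  p1 <- length(sd1$center); p2 <- length(sd2$center)
  A1 <- unstd_matrix_block(sd1, extra = 0)
  A2 <- unstd_matrix_block(sd2, extra = 0)
  n1 <- 2 + 2 * p1; n2 <- 2 + 2 * p2
  A <- diag(n1 + n2 + 3)
  A[seq_len(n1), seq_len(n1)] <- A1
  A[n1 + seq_len(n2), n1 + seq_len(n2)] <- A2
  A
}

# univariate analogue of make_objective (see likelihood.R)
#' @noRd
make_uni_objective <- function(cl, y, X, control, adapt = NULL) {
  p <- ncol(X)
  cache <- new.env(parent = emptyenv()); cache$psi <- NULL
  unpack <- function(psi) {
    list(omega = psi[1:2],
         sl = matrix(psi[2 + seq_len(2 * p)], ncol = 2),
         phi = min(max(plogis(psi[2 + 2 * p + 1]), 1e-9), 1 - 1e-9))
  }
  evalboth <- function(psi) {
    if (!is.null(cache$psi) && isTRUE(all.equal(psi, cache$psi, tolerance = 0)))
      return()
    u <- unpack(psi)
    res <- engine_uni(cl, y, X, u$omega, u$sl, u$phi, control,
                      want_grad = TRUE, adapt = adapt)
    g <- res$grad
    g[length(g)] <- g[length(g)] * u$phi * (1 - u$phi)
    cache$psi <- psi; cache$ll <- res$loglik; cache$grad <- g
  }
  list(fn = function(psi) { evalboth(psi); -cache$ll },
       gr = function(psi) { evalboth(psi); -cache$grad },
       adapt_at = function(psi) {
         u <- unpack(psi)
         engine_uni(cl, y, X, u$omega, u$sl, u$phi, control)$adapt
       },
       with_adapt = function(a) make_uni_objective(cl, y, X, control,
                                                   adapt = a))
}

# thresholds from marginal category frequencies, divided by the starting
# scale so the marginalized frequencies roughly match (Bridge attenuation)
#' @noRd
start_thresholds <- function(y, phi0) {
  n0 <- max(sum(y == 0), 0.5)
  log(c(max(sum(y == 1), 0.5), max(sum(y == 2), 0.5)) / n0) / phi0
}

#' @noRd
check_full_rank <- function(X, label) {
  if (ncol(X) == 0) return(invisible())
  const <- apply(X, 2, function(v) max(v) == min(v))
  if (any(const))
    abort(sprintf("Constant (or all-zero) predictor column(s) in %s: %s",
                  label, paste(colnames(X)[const], collapse = ", ")))
  Xi <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) {
    bad <- colnames(Xi)[q$pivot[(q$rank + 1):ncol(Xi)]]
    abort(sprintf("Rank-deficient design in %s; collinear column(s): %s",
                  label, paste(bad, collapse = ", ")))
  }
  invisible()
}

# BFGS from the default start plus jittered replicas (fixed jitter
# stream, so fits are deterministic).  With adaptive quadrature the node
# adaptation is frozen during each inner BFGS run -- making the
# objective/gradient pair exactly consistent -- and recomputed between
# runs until self-consistent (the re-adapted score meets `grad_tol`).
#' @noRd
run_starts <- function(obj, psi0, control) {
  one_start <- function(s) {
    psi <- s
    adapt <- if (control$adaptive)
      tryCatch(obj$adapt_at(psi), error = function(e) NULL) else NULL
    if (control$adaptive && is.null(adapt)) return(NULL)
    res <- NULL; gnorm <- Inf; value <- Inf; info <- NULL
    optim_code <- 0L
    for (round in seq_len(if (control$adaptive) 12 else 4)) {
      o <- if (is.null(adapt)) obj else obj$with_adapt(adapt)
      if (max(abs(o$gr(psi))) > 10 * control$grad_tol) {
        res <- tryCatch(
          optim(psi, o$fn, o$gr, method = "BFGS",
                control = list(maxit = control$maxit,
                               reltol = control$reltol)),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        psi <- res$par
        optim_code <- res$convergence
      }
      # Newton polish on the frozen objective; the Jacobian of the score
      # is reused as the observed information
      for (k in 1:4) {
        g <- o$gr(psi)
        if (max(abs(g)) <= 0.2 * control$grad_tol) break
        info <- fd_score_jacobian(o$gr, psi)
        step <- tryCatch(solve(info, -g), error = function(e) NULL)
        if (is.null(step))
          step <- tryCatch(solve(info + 1e-6 * diag(nrow(info)), -g),
                           error = function(e) NULL)
        if (is.null(step)) break
        if (max(abs(step)) > 1) step <- step / max(abs(step))
        f0 <- o$fn(psi); sc <- 1
        repeat {
          if (o$fn(psi + sc * step) <= f0 + 1e-12) { psi <- psi + sc * step; break }
          sc <- sc / 2
          if (sc < 1e-4) break
        }
      }
      if (!control$adaptive) {
        gnorm <- max(abs(o$gr(psi))); value <- o$fn(psi)
        if (gnorm <= control$grad_tol) break
      } else {
        adapt <- obj$adapt_at(psi)
        o2 <- obj$with_adapt(adapt)
        gnorm <- max(abs(o2$gr(psi))); value <- o2$fn(psi)
        if (gnorm <= control$grad_tol) break
      }
    }
    list(psi = psi, value = value, gnorm = gnorm, adapt = adapt,
         info = info, optim_convergence = optim_code, rounds = round,
         counts = if (!is.null(res)) res$counts else c(0L, 0L))
  }

  starts <- list(psi0)
  if (control$n_starts > 1) {
    jit <- with_seed_(101,
      lapply(seq_len(control$n_starts - 1), function(k)
        psi0 + rnorm(length(psi0), sd = 0.25)))
    starts <- c(starts, jit)
  }
  runs <- Filter(Negate(is.null), lapply(starts, one_start))
  if (!length(runs)) abort("All optimizer starts failed.")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  list(psi = best$psi, value = best$value, adapt = best$adapt,
       info = best$info,
       converged = (best$optim_convergence == 0 &&
                      best$gnorm <= control$grad_tol),
       diagnostics = list(grad_norm = best$gnorm,
                          optim_convergence = best$optim_convergence,
                          n_starts = length(runs),
                          adapt_rounds = best$rounds,
                          counts = best$counts))
}

# symmetrized central-difference Jacobian of the negative score; equals
# the observed information at the optimum
#' @noRd
fd_score_jacobian <- function(gr, psi) {
  np <- length(psi)
  J <- matrix(NA_real_, np, np)
  h <- 1e-5 * (1 + abs(psi))
  for (i in seq_len(np)) {
    up <- psi; up[i] <- up[i] + h[i]
    dn <- psi; dn[i] <- dn[i] - h[i]
    J[i, ] <- (gr(up) - gr(dn)) / (2 * h[i])
  }
  (J + t(J)) / 2
}

# covariance from the observed information (M approx -Hessian of loglik).
# Quasi-separated data make the information singular at numerical
# precision along the flat direction; eigenvalues at noise level are
# clamped, giving effectively infinite standard errors there (flagged)
# instead of failing the whole fit.  Indefinite information beyond noise
# level still invalidates the covariance.
#' @noRd
vcov_from_info <- function(M) {
  e <- tryCatch(eigen(M, symmetric = TRUE), error = function(err) NULL)
  if (is.null(e) || !all(is.finite(e$values)))
    return(list(vcov = NULL, ok = FALSE, clamped = FALSE))
  mx <- max(abs(e$values))
  if (!(mx > 0) || min(e$values) < -1e-8 * mx)
    return(list(vcov = NULL, ok = FALSE, clamped = FALSE))
  floor_ <- 1e-10 * mx
  clamped <- any(e$values < floor_)
  lam <- pmax(e$values, floor_)
  vc <- e$vectors %*% (t(e$vectors) / lam)
  ok <- all(is.finite(vc)) && all(diag(vc) > 0)
  list(vcov = vc, ok = ok, clamped = clamped)
}

#' @export
print.jb_fit <- function(x, ...) {
  cat(sprintf("<jb_fit> %s model: loglik %.3f on %d subjects in %d clusters\n",
              x$type, x$loglik, x$n_obs, x$n_clusters))
  if (x$type == "joint")
    cat(sprintf("  phi1 = %.3f, phi2 = %.3f, rho = %.3f\n",
                x$params$phi1, x$params$phi2, x$params$rho))
  else
    cat(sprintf("  outcome %s: phi = %.3f\n", x$outcome, x$params$phi))
  cat(sprintf("  converged: %s (score max-norm %.2g)\n",
              x$converged, x$diagnostics$grad_norm))
  invisible(x)
}
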