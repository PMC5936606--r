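#' Parameter vector of the joint model
#'
#' Bundles the parameters of the two baseline-category sub-models and the
#' bivariate Bridge intercept law: thresholds `omega` (outcome 1) and
#' `theta` (outcome 2), one per non-reference category; slope matrices
#' `alpha` and `beta` with one column per non-reference category; Bridge
#' scales `phi1`, `phi2` in (0, 1); and copula correlation `rho` in
#' (-1, 1).  The linear predictor of category c for subject j in cluster i
#' is \eqn{u_{ki} + \omega_c + x_j'\alpha_c}.
#'
#' @param omega,theta Numeric length-2 threshold vectors.
#' @param alpha,beta Slope matrices (`p x 2`; a vector is recycled into a
#'   two-column matrix with one row per predictor if `p = 1`, or may be
#'   omitted as `NULL` for intercept-only sub-models).
#' @param phi1,phi2 Bridge scales.
#' @param rho Copula correlation.
#' @return An object of class `jb_params`.
#' @export
jb_params <- function(omega, alpha = NULL, theta, beta = NULL,
                      phi1, phi2, rho = 0) {
  fix_slopes <- function(s) {
    if (is.null(s)) return(matrix(0, 0, 2))
    if (is.vector(s)) s <- matrix(s, ncol = 2)
    stopifnot(ncol(s) == 2)
    s
  }
  check_phi(phi1); check_phi(phi2)
  if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
  stopifnot(length(omega) == 2, length(theta) == 2)
  structure(list(omega = as.numeric(omega), alpha = fix_slopes(alpha),
                 theta = as.numeric(theta), beta = fix_slopes(beta),
                 phi1 = phi1, phi2 = phi2, rho = rho),
            class = "jb_params")
}

#' @export
print.jb_params <- function(x, ...) {
  cat("<jb_params>\n")
  cat("  omega:", signif(x$omega, 4), " theta:", signif(x$theta, 4), "\n")
  cat(sprintf("  %d + %d slopes; phi1 = %.3f, phi2 = %.3f, rho = %.3f\n",
              nrow(x$alpha), nrow(x$beta), x$phi1, x$phi2, x$rho))
  invisible(x)
}

# unconstrained packing: thresholds and slopes unchanged, phi via logit,
# rho via atanh
#' @noRd
par_pack <- function(pp) {
  c(pp$omega, as.numeric(pp$alpha), pp$theta, as.numeric(pp$beta),
    qlogis(pp$phi1), qlogis(pp$phi2), atanh(pp$rho))
}

#' @noRd
par_unpack <- function(psi, p1, p2) {
  i <- 0
  omega <- psi[i + 1:2]; i <- i + 2
  alpha <- matrix(psi[i + seq_len(2 * p1)], ncol = 2); i <- i + 2 * p1
  theta <- psi[i + 1:2]; i <- i + 2
  beta <- matrix(psi[i + seq_len(2 * p2)], ncol = 2); i <- i + 2 * p2
  # clamp the back-transforms away from the open-interval boundaries so
  # far-out line-search trials stay evaluable
  sq <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)
  jb_params(omega, alpha, theta, beta,
            phi1 = sq(plogis(psi[i + 1])), phi2 = sq(plogis(psi[i + 2])),
            rho = 2 * sq((tanh(psi[i + 3]) + 1) / 2, 1e-12) - 1)
}

#' Numerical controls for fitting
#'
#' @param nodes Gauss-Hermite nodes per dimension (>= 3; default 7, which
#'   with per-cluster adaptation resolves the integrand to well below the
#'   optimizer tolerance; see the methods vignette).
#' @param adaptive Centre and rescale the quadrature per cluster at the
#'   mode/curvature of the log-integrand (default) or use the plain rule.
#' @param n_starts Number of optimizer starts: the deterministic default
#'   start plus `n_starts - 1` jittered replicas (fixed internal seed, so
#'   fits remain reproducible).
#' @param maxit,reltol BFGS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param grad_tol Max-norm of the score at the optimum required to report
#'   convergence.
#' @param fix_rho Optionally hold the copula correlation fixed at this
#'   value during a joint fit (e.g. `0` for an independence fit); `NULL`
#'   estimates it.
#' @return A list of class `jb_control`.
#' @export
jb_control <- function(nodes = 7L, adaptive = TRUE, n_starts = 3L,
                       maxit = 500L, reltol = 1e-10, grad_tol = 1e-4,
                       fix_rho = NULL) {
  if (nodes < 3) abort("`nodes` must be at least 3.")
  if (!is.null(fix_rho) && abs(fix_rho) >= 1)
    abort("`fix_rho` must lie strictly inside (-1, 1).")
  structure(list(nodes = as.integer(nodes), adaptive = isTRUE(adaptive),
                 n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 reltol = reltol, grad_tol = grad_tol, fix_rho = fix_rho),
            class = "jb_control")
}

#' Conditional category probabilities of one sub-model
#'
#' Baseline-category logits: given a random-intercept value `u` and linear
#' predictors \eqn{\eta_c} for the non-reference categories, the
#' probability of non-reference category c is
#' \eqn{e^{u+\eta_c} / (1 + \sum_{c'} e^{u+\eta_{c'}})} and the reference
#' probability is \eqn{1 / (1 + \sum_{c'} e^{u+\eta_{c'}})}.  Computed with
#' log-sum-exp so finite inputs never produce NaN.
#'
#' @param eta Numeric vector of length 2 (one linear predictor per
#'   non-reference category) or an `n x 2` matrix.
#' @param u Random-intercept value (scalar, or vector of length n).
#' @return Probabilities summing to 1 per row, non-reference categories
#'   first, reference last.
#' @examples
#' category_probs(c(log(2), 0))   # (0.5, 0.25, 0.25)
#' @export
category_probs <- function(eta, u = 0) {
  if (is.vector(eta)) eta <- matrix(eta, ncol = 2)
  stopifnot(ncol(eta) == 2, all(is.finite(eta)), all(is.finite(u)))
  l <- eta + u
  m <- pmax(0, l[, 1], l[, 2])
  d <- exp(-m) + exp(l[, 1] - m) + exp(l[, 2] - m)
  out <- cbind(exp(l[, 1] - m) / d, exp(l[, 2] - m) / d, exp(-m) / d)
  colnames(out) <- c("cat1", "cat2", "ref")
  if (nrow(out) == 1) drop(out) else out
}

# `adapt` freezes the per-cluster quadrature centring/scaling (ncl x 5
# matrix as returned in $adapt); NULL lets the kernel self-adapt.
#' @noRd
engine_joint <- function(jbd, params, control, want_grad = FALSE,
                         adapt = NULL) {
  gh <- gauss_hermite_normal(control$nodes)
  agq_joint_cpp(cluster_offsets(jbd$cluster),
                jbd$y1, jbd$X1, params$omega, params$alpha,
                jbd$y2, jbd$X2, params$theta, params$beta,
                params$phi1, params$phi2, params$rho,
                gh$nodes, gh$weights, control$adaptive, want_grad,
                adapt %||% matrix(0, 0, 0))
}

#' @noRd
engine_uni <- function(cl, y, X, omega, slopes, phi, control,
                       want_grad = FALSE, adapt = NULL) {
  gh <- gauss_hermite_normal(control$nodes)
  agq_uni_cpp(cluster_offsets(cl), y, X, omega, slopes, phi,
              gh$nodes, gh$weights, control$adaptive, want_grad,
              adapt %||% matrix(0, 0, 0))
}

#' Marginal log-likelihood of the joint model
#'
#' Evaluates \eqn{\sum_i \log \int\!\!\int \prod_j
#' P(y_{1ij}\mid u_1)\,P(y_{2ij}\mid u_2)\; dF(u_1,u_2;\phi_1,\phi_2,\rho)}
#' by per-cluster (adaptive) tensor Gauss-Hermite quadrature on the
#' Gaussian-copula scale.
#'
#' @param data A `jb_data` from [build_design()], or a raw data frame (then
#'   `spec` is used to build the design).
#' @param params A [jb_params()] whose slope dimensions match the design.
#' @param control A [jb_control()].
#' @param spec Used only when `data` is a raw data frame.
#' @return The total log-likelihood, with the per-cluster contributions in
#'   attribute `"by_cluster"`.
#' @export
total_loglik <- function(data, params, control = jb_control(),
                         spec = default_spec()) {
  jbd <- if (inherits(data, "jb_data")) data else build_design(data, spec)
  if (nrow(jbd$data) == 0) abort("Empty dataset.")
  stopifnot(nrow(params$alpha) == ncol(jbd$X1),
            nrow(params$beta) == ncol(jbd$X2))
  res <- engine_joint(jbd, params, control)
  structure(res$loglik, by_cluster = as.numeric(res$by_cluster))
}

#' Log-likelihood contribution of a single cluster
#'
#' @inheritParams total_loglik
#' @return A single number.
#' @export
cluster_loglik <- function(data, params, control = jb_control(),
                           spec = default_spec()) {
  jbd <- if (inherits(data, "jb_data")) data else build_design(data, spec)
  if (nrow(jbd$data) == 0) abort("Empty cluster.")
  if (length(unique(jbd$cluster)) != 1)
    abort("`cluster_loglik()` expects rows from a single cluster.")
  as.numeric(total_loglik(jbd, params, control))
}

# negative loglik / gradient pair on the unconstrained scale, with a
# one-slot cache so optim's alternating fn/gr calls cost one evaluation.
# With `adapt` supplied the quadrature is frozen, making fn and gr an
# exactly consistent smooth pair (the inner problem of the re-adaptation
# loop in run_starts); self-adaptive objectives are used only for
# standalone likelihood evaluation.
#' @noRd
make_objective <- function(jbd, control, adapt = NULL) {
  p1 <- ncol(jbd$X1); p2 <- ncol(jbd$X2)
  cache <- new.env(parent = emptyenv())
  cache$psi <- NULL
  pin <- function(psi) {
    if (!is.null(control$fix_rho)) psi[length(psi)] <- atanh(control$fix_rho)
    psi
  }
  evalboth <- function(psi) {
    if (!is.null(cache$psi) && isTRUE(all.equal(psi, cache$psi, tolerance = 0)))
      return()
    pp <- par_unpack(pin(psi), p1, p2)
    res <- engine_joint(jbd, pp, control, want_grad = TRUE, adapt = adapt)
    g <- res$grad
    nd <- length(g)
    # chain rule to the unconstrained scale
    g[nd - 2] <- g[nd - 2] * pp$phi1 * (1 - pp$phi1)
    g[nd - 1] <- g[nd - 1] * pp$phi2 * (1 - pp$phi2)
    g[nd]     <- if (is.null(control$fix_rho)) g[nd] * (1 - pp$rho^2) else 0
    cache$psi <- psi
    cache$ll <- res$loglik
    cache$grad <- g
  }
  list(
    fn = function(psi) { evalboth(psi); -cache$ll },
    gr = function(psi) { evalboth(psi); -cache$grad },
    adapt_at = function(psi) {
      pp <- par_unpack(pin(psi), p1, p2)
      engine_joint(jbd, pp, control)$adapt
    },
    with_adapt = function(a) make_objective(jbd, control, adapt = a)
  )
}
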