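#' The Bridge distribution for logit random intercepts
#'
#' Density, distribution function, quantile function and random generation
#' for the Bridge distribution with scale parameter `phi` in (0, 1).  The
#' Bridge law is the random-intercept distribution under which a logistic
#' (logit-link) model retains its logistic form after the intercept is
#' integrated out: if \eqn{u \sim \mathrm{Bridge}(\phi)} then
#' \deqn{\int \mathrm{expit}(u + \eta) f(u;\phi)\,du = \mathrm{expit}(\phi\eta),}
#' so conditional (within-cluster) log-odds-ratios are attenuated by the
#' factor \eqn{\phi} marginally but keep the odds-ratio interpretation.
#'
#' The density is
#' \deqn{f(u;\phi) = \frac{1}{2\pi}\,
#'   \frac{\sin(\phi\pi)}{\cosh(\phi u) + \cos(\phi\pi)},}
#' symmetric about 0 with variance \eqn{(\pi^2/3)(\phi^{-2} - 1)}; as
#' \eqn{\phi \to 1} it degenerates to a point mass at 0.  The quantile
#' function has the closed form
#' \deqn{F^{-1}(p) = \frac{1}{\phi}
#'   \log\!\frac{\sin(\phi\pi p)}{\sin(\phi\pi(1-p))};}
#' `pbridge()` inverts it numerically by bisection (tolerance 1e-10 on `p`)
#' rather than relying on an algebraic CDF.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities in (0, 1).
#' @param n Number of draws.
#' @param phi Bridge scale parameter, a single number strictly between 0
#'   and 1.  Small `phi` means a heavy, dispersed intercept distribution;
#'   `phi` near 1 means almost no cluster heterogeneity.
#' @param seed Optional integer seed; when supplied, draws are taken from a
#'   temporarily seeded RNG stream and the caller's RNG state is restored.
#'
#' @return `dbridge()`, `pbridge()` and `qbridge()` return numeric vectors;
#'   `rbridge()` returns `n` draws; `bridge_variance()` the variance.
#'
#' @examples
#' dbridge(0, phi = 0.5)            # 1 / (2 * pi)
#' qbridge(0.5, phi = 0.3)          # 0 by symmetry
#' bridge_variance(0.5)             # pi^2
#' u <- rbridge(1000, phi = 0.6, seed = 1)
#' @name bridge
NULL

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || !is.finite(phi) ||
      phi <= 0 || phi >= 1)
    abort("`phi` must be a single number strictly between 0 and 1.")
  invisible(phi)
}

#' @rdname bridge
#' @export
dbridge <- function(x, phi) {
  check_phi(phi)
  sin(phi * pi) / (2 * pi) / (cosh(phi * x) + cos(phi * pi))
}

#' @rdname bridge
#' @export
qbridge <- function(p, phi) {
  check_phi(phi)
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    abort("`p` must lie strictly inside (0, 1).")
  (log(sin(phi * pi * p)) - log(sin(phi * pi * (1 - p)))) / phi
}

#' @rdname bridge
#' @export
pbridge <- function(q, phi) {
  check_phi(phi)
  lo <- rep(1e-15, length(q))
  hi <- rep(1 - 1e-15, length(q))
  for (it in 1:60) {                    # 2^-60 < 1e-10 interval width
    mid <- (lo + hi) / 2
    below <- qbridge(mid, phi) < q
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

#' @rdname bridge
#' @export
rbridge <- function(n, phi, seed = NULL) {
  check_phi(phi)
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    abort("`n` must be a positive count.")
  with_seed_(seed, qbridge(runif(n), phi))
}

#' @rdname bridge
#' @export
bridge_variance <- function(phi) {
  check_phi(phi)
  (pi^2 / 3) * (1 / phi^2 - 1)
}

#' Correlated bivariate Bridge random intercepts
#'
#' Draws pairs \eqn{(u_1, u_2)} whose margins are Bridge distributions with
#' scales `phi1`, `phi2`, coupled by a Gaussian copula with correlation
#' `rho`: a bivariate standard normal pair \eqn{(z_1, z_2)} with correlation
#' \eqn{\rho} is mapped through \eqn{u_k = F_k^{-1}(\Phi(z_k))}.  The copula
#' preserves both margins exactly; `rho = 0` gives independent intercepts
#' and the rank correlation of the pairs is monotone in `rho`.
#'
#' @param n Number of pairs.
#' @param phi1,phi2 Bridge scales of the two margins, each in (0, 1).
#' @param rho Copula correlation, strictly between -1 and 1.
#' @inheritParams bridge
#' @return A tibble with columns `u1`, `u2`.
#' @examples
#' rbridge2(5, phi1 = 0.6, phi2 = 0.7, rho = 0.5, seed = 1)
#' @export
rbridge2 <- function(n, phi1, phi2, rho, seed = NULL) {
  check_phi(phi1); check_phi(phi2)
  if (!is.numeric(rho) || length(rho) != 1 || abs(rho) >= 1)
    abort("`rho` must be a single number strictly between -1 and 1.")
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    abort("`n` must be a positive count.")
  with_seed_(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    tibble::tibble(u1 = qbridge(pnorm(z1), phi1),
                   u2 = qbridge(pnorm(z2), phi2))
  })
}

#' Marginal success probability under a Bridge random intercept
#'
#' The defining property of the Bridge family: integrating a logistic
#' within-cluster probability \eqn{\mathrm{expit}(u + \eta)} over
#' \eqn{u \sim \mathrm{Bridge}(\phi)} returns a logistic probability with
#' the linear predictor attenuated by \eqn{\phi}.
#'
#' @param eta Linear predictor (vectorised).
#' @param phi Bridge scale in (0, 1).
#' @return `plogis(phi * eta)`.
#' @examples
#' bridge_marginal_prob(1, phi = 0.5)  # plogis(0.5)
#' @export
bridge_marginal_prob <- function(eta, phi) {
  check_phi(phi)
  plogis(phi * eta)
}
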