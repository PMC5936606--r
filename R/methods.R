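#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# index map from the unconstrained parameter vector to labelled rows
#' @noRd
coef_map <- function(x) {
  if (x$type == "joint") {
    s <- x$spec
    p1 <- length(x$terms1); p2 <- length(x$terms2)
    con1 <- paste(setdiff(s$categories1, s$ref1), "vs", s$ref1)
    con2 <- paste(setdiff(s$categories2, s$ref2), "vs", s$ref2)
    fixed <- tibble::tibble(
      index = c(1:2, 2 + seq_len(2 * p1),
                2 + 2 * p1 + 1:2, 2 + 2 * p1 + 2 + seq_len(2 * p2)),
      outcome = c(rep(s$outcome1, 2 + 2 * p1), rep(s$outcome2, 2 + 2 * p2)),
      contrast = c(con1, rep(con1, each = p1),
                   con2, rep(con2, each = p2)),
      term = c(rep("(threshold)", 2), rep(x$terms1, 2),
               rep("(threshold)", 2), rep(x$terms2, 2)))
    nd <- 2 + 2 * p1 + 2 + 2 * p2
    disp <- tibble::tibble(index = nd + 1:3,
                           term = c("phi1", "phi2", "rho"),
                           trans = c("plogis", "plogis", "tanh"))
  } else {
    s <- x$spec
    p <- length(x$terms1)
    cats <- if (x$which == 1) s$categories1 else s$categories2
    ref <- if (x$which == 1) s$ref1 else s$ref2
    con <- paste(setdiff(cats, ref), "vs", ref)
    fixed <- tibble::tibble(
      index = c(1:2, 2 + seq_len(2 * p)),
      outcome = x$outcome,
      contrast = c(con, rep(con, each = p)),
      term = c(rep("(threshold)", 2), rep(x$terms1, 2)))
    disp <- tibble::tibble(index = 2 + 2 * p + 1,
                           term = "phi", trans = "plogis")
  }
  list(fixed = fixed, disp = disp)
}

#' Tidy a fitted joint or univariate model
#'
#' One row per coefficient.  Fixed-effect rows are on the conditional
#' (within-cluster) log-odds scale; `exponentiate = TRUE` turns estimates
#' and interval bounds into odds ratios.  Dispersion rows (`phi1`, `phi2`,
#' `rho` -- or `phi` for a univariate fit) are reported on their natural
#' scale with delta-method standard errors and endpoint-transformed
#' confidence bounds.
#'
#' @param x A `jb_fit`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param conf.level Confidence level (default 0.95).
#' @param component `"fixed"`, `"dispersion"` or `"all"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.jb_fit <- function(x, exponentiate = FALSE, conf.level = 0.95,
                        component = c("all", "fixed", "dispersion"), ...) {
  component <- match.arg(component)
  q <- qnorm(1 - (1 - conf.level) / 2)
  cm <- coef_map(x)
  se_psi <- if (!is.null(x$vcov)) sqrt(pmax(diag(x$vcov), 0)) else
    rep(NA_real_, length(x$psi))

  fx <- cm$fixed
  est <- x$psi[fx$index]; se <- se_psi[fx$index]
  fixed <- dplyr::mutate(
    fx[setdiff(names(fx), "index")],
    component = "fixed",
    estimate = est, std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(-abs(.data$statistic)),
    conf.low = est - q * se, conf.high = est + q * se)
  if (exponentiate)
    fixed <- dplyr::mutate(fixed,
                           estimate = exp(.data$estimate),
                           conf.low = exp(.data$conf.low),
                           conf.high = exp(.data$conf.high))

  dp <- cm$disp
  psi_d <- x$psi[dp$index]; se_d <- se_psi[dp$index]
  tr <- function(f, v) vapply(seq_along(v), function(i)
    if (dp$trans[i] == "plogis") plogis(v[i]) else tanh(v[i]), numeric(1))
  nat <- tr(dp$trans, psi_d)
  deriv <- ifelse(dp$trans == "plogis", nat * (1 - nat), 1 - nat^2)
  disp <- tibble::tibble(
    outcome = NA_character_, contrast = NA_character_, term = dp$term,
    component = "dispersion",
    estimate = nat, std.error = se_d * deriv,
    statistic = NA_real_, p.value = NA_real_,
    conf.low = tr(dp$trans, psi_d - q * se_d),
    conf.high = tr(dp$trans, psi_d + q * se_d))

  out <- switch(component,
                fixed = fixed,
                dispersion = disp,
                all = dplyr::bind_rows(fixed, disp))
  tibble::as_tibble(out)
}

#' Model-level summary of a fitted model
#'
#' @param x A `jb_fit`.
#' @param ... Unused.
#' @return A one-row tibble with log-likelihood, information criteria,
#'   sizes, dispersion parameters and the convergence flag.
#' @export
glance.jb_fit <- function(x, ...) {
  df <- length(x$psi)
  base <- tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * df,
    BIC = -2 * x$loglik + log(x$n_obs) * df,
    df = df, nobs = x$n_obs, n_clusters = x$n_clusters,
    converged = x$converged)
  if (x$type == "joint")
    dplyr::mutate(base, phi1 = x$params$phi1, phi2 = x$params$phi2,
                  rho = x$params$rho)
  else
    dplyr::mutate(base, phi = x$params$phi)
}

#' Odds-ratio table with Wald confidence intervals
#'
#' One row per predictor and non-reference contrast: the odds ratio
#' `exp(b)`, endpoint-transformed Wald bounds `exp(b +/- q se)` with `q`
#' the two-sided normal quantile (1.959964 at the 0.95 level), and the
#' two-sided normal p-value of `b / se`.  By Wald duality an interval
#' containing 1 corresponds exactly to `p >= 1 - level`.
#'
#' @param fit A converged `jb_fit`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `outcome`, `contrast`, `term`, `estimate`
#'   (log-odds), `std.error`, `or`, `conf.low`, `conf.high`, `p.value` and
#'   `flag` (non-`NA` when a standard error is unavailable).
#' @export
wald_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "jb_fit"))
  check_prob(level, "level")
  td <- tidy.jb_fit(fit, exponentiate = FALSE, conf.level = level,
                    component = "fixed")
  td <- dplyr::filter(td, .data$term != "(threshold)")
  q <- qnorm(1 - (1 - level) / 2)
  dplyr::transmute(
    td,
    outcome = .data$outcome, contrast = .data$contrast, term = .data$term,
    estimate = .data$estimate, std.error = .data$std.error,
    or = exp(.data$estimate),
    conf.low = exp(.data$estimate - q * .data$std.error),
    conf.high = exp(.data$estimate + q * .data$std.error),
    p.value = .data$p.value,
    flag = ifelse(is.finite(.data$std.error) & .data$std.error > 0,
                  NA_character_, "standard error not positive"))
}

#' Forest plot of fitted odds ratios
#'
#' @param object A `jb_fit`.
#' @param level Confidence level for the intervals.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jb_fit <- function(object, level = 0.95, ...) {
  d <- wald_intervals(object, level = level)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome, .data$contrast),
                        scales = "free_x") +
    ggplot2::labs(x = sprintf("Odds ratio (%d%% CI, log scale)",
                              round(100 * level)),
                  y = NULL)
}
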