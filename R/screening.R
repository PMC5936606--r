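#' Univariate screening of candidate predictors
#'
#' The variable-entry stage of the analysis: for each candidate predictor
#' and each outcome, a univariate multilevel nominal logistic model with a
#' Bridge random intercept is fitted and compared with the intercept-only
#' multilevel model by a likelihood-ratio test on 2 degrees of freedom
#' (the predictor's two category contrasts jointly).  A predictor enters
#' the joint model when its p-value falls below `threshold` (the
#' conventional liberal 0.20) for at least one outcome.
#'
#' A predictor whose univariate fit does not converge is flagged
#' `"undetermined"`, excluded from the selection, and reported with a
#' message rather than silently dropped.
#'
#' @param data A data frame with both outcomes, the cluster column and the
#'   candidate predictors.
#' @param candidates Character vector of predictor columns; defaults to
#'   the union of the predictors named in `spec`.
#' @param threshold Entry p-value threshold in \[0, 1\] (default 0.20).
#' @param spec A [joint_spec()] supplying outcome/cluster names and coding.
#' @param control A [jb_control()]; screening defaults to single-start
#'   fits, which are ample for one-predictor models.
#' @return A tibble of class `jb_screen` with one row per predictor x
#'   outcome (`statistic`, `df`, `p.value`, `selected`, `status`), the
#'   threshold in attribute `"threshold"` and the union entry set in
#'   attribute `"selected"`.
#' @export
screen_predictors <- function(data, candidates = NULL, threshold = 0.20,
                              spec = default_spec(),
                              control = jb_control(n_starts = 1)) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    abort("`threshold` must be a single probability in [0, 1].")
  candidates <- candidates %||% union(spec$predictors1, spec$predictors2)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols))
    abort(paste0("Candidate predictor(s) not in data: ",
                 paste(missing_cols, collapse = ", ")))

  outcomes <- c(spec$outcome1, spec$outcome2)
  nulls <- lapply(c("outcome1", "outcome2"), function(o)
    fit_univariate(data, outcome = o, predictor = NULL,
                   spec = spec, control = control))

  rows <- purrr::map_dfr(candidates, function(pr) {
    purrr::map_dfr(1:2, function(k) {
      alt <- tryCatch(
        fit_univariate(data, outcome = paste0("outcome", k), predictor = pr,
                       spec = spec, control = control),
        error = function(e) NULL)
      if (is.null(alt) || !isTRUE(alt$converged) ||
          !isTRUE(nulls[[k]]$converged)) {
        inform(sprintf("screen_predictors: univariate fit undetermined for `%s` (%s).",
                       pr, outcomes[k]))
        return(tibble::tibble(predictor = pr, outcome = outcomes[k],
                              statistic = NA_real_, df = 2L,
                              p.value = NA_real_, selected = FALSE,
                              status = "undetermined"))
      }
      lr <- 2 * (alt$loglik - nulls[[k]]$loglik)
      lr <- max(lr, 0)
      p <- pchisq(lr, df = 2, lower.tail = FALSE)
      tibble::tibble(predictor = pr, outcome = outcomes[k],
                     statistic = lr, df = 2L, p.value = p,
                     selected = p < threshold, status = "ok")
    })
  })

  selected <- unique(rows$predictor[rows$selected])
  structure(rows, class = c("jb_screen", class(rows)),
            threshold = threshold, selected = selected)
}

#' @export
print.jb_screen <- function(x, ...) {
  cat(sprintf("<jb_screen> threshold %.2f; selected: %s\n",
              attr(x, "threshold"),
              if (length(attr(x, "selected")))
                paste(attr(x, "selected"), collapse = ", ")
              else "(none)"))
  NextMethod()
}

#' @export
autoplot.jb_screen <- function(object, ...) {
  thr <- attr(object, "threshold")
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p.value, y = .data$predictor,
                                  colour = .data$outcome)) +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Univariate LRT p-value (log scale)", y = NULL,
                  colour = NULL)
}
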