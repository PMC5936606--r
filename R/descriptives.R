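#' Cross-tabulate two categorical variables
#'
#' Observed counts with row, column and grand totals -- the machinery
#' behind the outcome-association table (birth-weight class by
#' gestational-age class).
#'
#' @param data A data frame.
#' @param var_row,var_col Column names (bare or quoted).
#' @return An object of class `jb_xtab` wrapping the count matrix.
#' @examples
#' coh <- simulate_cohort(seed = 1,
#'                        config = cohort_config(n_clusters = 5, n_mothers = 300))
#' crosstab(coh, birth_weight, gestational_age)
#' @export
crosstab <- function(data, var_row, var_col) {
  vr <- col_name(rlang::enquo(var_row), names(data))
  vc <- col_name(rlang::enquo(var_col), names(data))
  for (nm in c(vr, vc))
    if (!nm %in% names(data)) abort(sprintf("Missing column `%s`.", nm))
  xr <- data[[vr]]; xc <- data[[vc]]
  if (is.numeric(xr) || is.numeric(xc))
    abort("Both variables must be categorical.")
  as_fct <- function(x) if (is.factor(x)) x else factor(x)
  tab <- table(as_fct(xr), as_fct(xc))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  new_jb_xtab(m, vr, vc)
}

#' @noRd
new_jb_xtab <- function(m, var_row = "row", var_col = "col") {
  stopifnot(is.matrix(m), all(m >= 0))
  structure(list(counts = m, var_row = var_row, var_col = var_col),
            class = "jb_xtab")
}

#' Build a contingency table from a count matrix
#'
#' For printed tables (published cross-tabs) where only the cell counts
#' are available.
#'
#' @param counts A numeric matrix of non-negative counts with dimnames.
#' @param var_row,var_col Variable labels.
#' @return A `jb_xtab`.
#' @export
as_crosstab <- function(counts, var_row = "row", var_col = "col") {
  new_jb_xtab(as.matrix(counts), var_row, var_col)
}

#' @export
print.jb_xtab <- function(x, ...) {
  m <- x$counts
  full <- rbind(cbind(m, Total = rowSums(m)),
                Total = c(colSums(m), sum(m)))
  cat(sprintf("<jb_xtab> %s x %s (n = %d)\n", x$var_row, x$var_col, sum(m)))
  print(full)
  invisible(x)
}

#' @export
tidy.jb_xtab <- function(x, ...) {
  m <- x$counts
  tibble::tibble(
    !!x$var_row := rep(rownames(m), times = ncol(m)),
    !!x$var_col := rep(colnames(m), each = nrow(m)),
    n = as.integer(m))
}

#' Pearson chi-square test of independence
#'
#' The plain Pearson statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts \eqn{E = (\text{row total})(\text{column total}) / n}, no
#' continuity correction and no small-cell exclusion, on
#' \eqn{(r-1)(c-1)} degrees of freedom.  Rows or columns whose margin is
#' zero are dropped with a warning and the degrees of freedom adjusted.
#'
#' @param x A `jb_xtab`, matrix or table of counts.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @examples
#' chisq_pearson(matrix(c(10, 0, 0, 10), 2))
#' @export
chisq_pearson <- function(x) {
  m <- if (inherits(x, "jb_xtab")) x$counts else as.matrix(x)
  if (sum(m) <= 0) abort("Table has no observations.")
  rz <- rowSums(m) == 0; cz <- colSums(m) == 0
  if (any(rz) || any(cz)) {
    warn(sprintf("Dropping %d zero-margin row(s) and %d column(s); df adjusted.",
                 sum(rz), sum(cz)))
    m <- m[!rz, !cz, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    abort("Need at least 2 rows and 2 columns with non-zero margins.")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = as.integer(ct$parameter),
                 p.value = unname(ct$p.value))
}

#' Category prevalences of an outcome
#'
#' Category count over total, times 100.  Full precision is kept; the
#' print method rounds to one decimal as in standard reporting.
#'
#' @param data A data frame.
#' @param outcome Outcome column (bare or quoted name).
#' @param categories Optional category ordering; defaults to factor levels
#'   or order of appearance.
#' @return A tibble: `category`, `n`, `percent`.
#' @export
prevalence <- function(data, outcome, categories = NULL) {
  oc <- col_name(rlang::enquo(outcome), names(data))
  if (!oc %in% names(data)) abort(sprintf("Missing column `%s`.", oc))
  x <- data[[oc]]
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("No non-missing outcome values.")
  lev <- categories %||% (if (is.factor(x)) levels(x) else unique(as.character(x)))
  n <- as.integer(table(factor(as.character(x), levels = lev)))
  tibble::tibble(category = lev, n = n, percent = 100 * n / sum(n))
}

#' Group summaries with tests
#'
#' The descriptive-table stage: for each variable, per-outcome-group
#' summaries plus a test of homogeneity across groups.  Continuous
#' variables get mean and SD per group with a one-way ANOVA p-value;
#' categorical variables get counts with row percentages (each variable
#' level summing to 100 across groups) and a Pearson chi-square p-value.
#'
#' @param data A data frame.
#' @param group Grouping column (one of the outcomes; bare or quoted).
#' @param vars Variables to summarise; defaults to all other columns.
#' @return A list of class `jb_groupsum` with tibbles `continuous`,
#'   `categorical` and `tests`.
#' @export
group_summary <- function(data, group, vars = NULL) {
  gc <- col_name(rlang::enquo(group), names(data))
  if (!gc %in% names(data)) abort(sprintf("Missing column `%s`.", gc))
  vars <- vars %||% setdiff(names(data), gc)
  g <- data[[gc]]
  if (!is.factor(g)) g <- factor(g)
  empty <- levels(g)[table(g) == 0]
  if (length(empty))
    warn(paste0("Empty group(s): ", paste(empty, collapse = ", ")))

  cont <- list(); cate <- list(); tests <- list()
  for (v in vars) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    if (is.numeric(x)) {
      d <- tibble::tibble(g = g[ok], x = x[ok])
      cont[[v]] <- d |>
        dplyr::group_by(.data$g) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$x),
                         sd = sd(.data$x), .groups = "drop") |>
        dplyr::mutate(variable = v, .before = 1) |>
        dplyr::rename(group = "g")
      p <- tryCatch({
        fit <- aov(x ~ g, data = d)
        summary(fit)[[1]][["Pr(>F)"]][1]
      }, error = function(e) NA_real_)
      tests[[v]] <- tibble::tibble(variable = v, test = "one-way ANOVA",
                                   p.value = p)
    } else {
      tab <- table(factor(as.character(x[ok])), g[ok])
      pct <- 100 * prop.table(tab, margin = 1)
      cate[[v]] <- tibble::tibble(
        variable = v,
        level = rep(rownames(tab), times = ncol(tab)),
        group = rep(colnames(tab), each = nrow(tab)),
        n = as.integer(tab), percent = as.numeric(pct))
      p <- tryCatch(chisq_pearson(as.matrix(tab))$p.value,
                    error = function(e) NA_real_)
      tests[[v]] <- tibble::tibble(variable = v, test = "Pearson chi-square",
                                   p.value = p)
    }
  }
  structure(list(continuous = dplyr::bind_rows(cont),
                 categorical = dplyr::bind_rows(cate),
                 tests = dplyr::bind_rows(tests),
                 group = gc),
            class = "jb_groupsum")
}

#' @export
print.jb_groupsum <- function(x, digits = 1, ...) {
  cat(sprintf("<jb_groupsum> by %s\n", x$group))
  if (nrow(x$continuous)) {
    cat("Continuous (mean ± SD):\n")
    d <- dplyr::mutate(x$continuous,
                       value = sprintf("%.*f ± %.*f", digits + 1,
                                       .data$mean, digits + 1, .data$sd))
    print(tidyr::pivot_wider(d[c("variable", "group", "value")],
                             names_from = "group", values_from = "value"))
  }
  if (nrow(x$categorical)) {
    cat("Categorical (n (%)):\n")
    d <- dplyr::mutate(x$categorical,
                       value = sprintf("%d (%.*f)", .data$n, digits,
                                       .data$percent))
    print(tidyr::pivot_wider(d[c("variable", "level", "group", "value")],
                             names_from = "group", values_from = "value"))
  }
  cat("Tests:\n"); print(x$tests)
  invisible(x)
}

#' Published outcome group sizes
#'
#' The printed per-category group sizes of both outcomes
#' (244/4149/22 and 213/4078/124 of 4415), shipped as a CSV fixture.
#'
#' @return A tibble: `outcome`, `category`, `n`.
#' @export
published_group_sizes <- function() {
  path <- system.file("extdata", "group_sizes.csv", package = "jointbridge")
  readr::read_csv(path, show_col_types = FALSE)
}

#' The published outcome cross-tabulation
#'
#' The 3x3 birth-weight class by gestational-age class table of printed
#' counts shipped with the package (CSV under `inst/extdata`), used as a
#' fixture for the association chi-square.
#'
#' @return A `jb_xtab` with 4415 observations.
#' @export
published_outcome_crosstab <- function() {
  path <- system.file("extdata", "outcome_crosstab.csv",
                      package = "jointbridge")
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  new_jb_xtab(m, "birth_weight", "gestational_age")
}
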