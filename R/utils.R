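#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# A NULL seed leaves the global stream untouched.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::local_seed(as.integer(seed))
  force(code)
}

# Gauss-Hermite rule recast for a standard normal kernel:
# sum(w * f(t)) approximates E[f(Z)], Z ~ N(0, 1).  Golub-Welsch via the
# symmetric tridiagonal Jacobi matrix of the Hermite recurrence.
#' @noRd
gauss_hermite_normal <- function(m) {
  stopifnot(m >= 1)
  if (m == 1) return(list(nodes = 0, weights = 1))
  i <- seq_len(m - 1)
  J <- matrix(0, m, m)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values * sqrt(2)
  weights <- e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord] / sum(weights))
}

# Column selection accepting either a bare column name or a character
# scalar (possibly computed), quosure in.  A bare symbol matching a data
# column wins; otherwise the quosure is evaluated to a string.
#' @noRd
col_name <- function(q, data_names) {
  if (rlang::quo_is_symbol(q) && rlang::as_name(q) %in% data_names)
    return(rlang::as_name(q))
  val <- tryCatch(rlang::eval_tidy(q), error = function(e) NULL)
  if (is.character(val) && length(val) == 1) return(val)
  if (rlang::quo_is_symbol(q)) return(rlang::as_name(q))
  abort("Supply a column as a bare name or a single string.")
}

#' @noRd
check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a single number in %s.", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}
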