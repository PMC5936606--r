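#' Specify the joint two-outcome multilevel model
#'
#' A model specification names the two categorical outcome columns with
#' their category sets and reference levels, the cluster column, and the
#' predictors entering each sub-model.  Each outcome must have exactly
#' three categories, one of which is the reference of its
#' baseline-category logits (the perinatal defaults: "term" for
#' gestational age and "normal" for birth weight).
#'
#' Categorical predictors must be binary; their reference level (coded 0)
#' is looked up in `references`, which is merged over the package defaults
#' ("No", "Female", "Undergraduate", "Housewife", "Wanted", "1" and
#' "Singleton" are reference labels).  Numeric predictors pass through
#' unchanged.
#'
#' @param outcome1,outcome2 Names of the two outcome columns.
#' @param predictors1,predictors2 Character vectors of predictor columns
#'   for each sub-model (may be empty).
#' @param cluster Name of the cluster (hospital) id column.
#' @param categories1,categories2 Category labels of each outcome.
#' @param ref1,ref2 Reference categories; must appear in the category sets.
#' @param references Named list mapping binary predictor columns to their
#'   reference label, merged over the built-in defaults.
#' @return An object of class `jb_spec`.
#' @examples
#' joint_spec(predictors1 = c("mother_age", "preeclampsia"),
#'            predictors2 = c("bmi", "infant_sex"))
#' @export
joint_spec <- function(outcome1 = "gestational_age",
                       outcome2 = "birth_weight",
                       predictors1 = character(),
                       predictors2 = character(),
                       cluster = "hospital",
                       categories1 = c("preterm", "term", "postterm"),
                       categories2 = c("LBW", "normal", "macrosomia"),
                       ref1 = "term",
                       ref2 = "normal",
                       references = list()) {
  if (length(categories1) != 3 || length(categories2) != 3)
    abort("Each outcome must have exactly three categories.")
  if (!ref1 %in% categories1 || !ref2 %in% categories2)
    abort("Reference categories must be members of the category sets.")
  refs <- modifyList(default_reference_levels(), references)
  structure(
    list(outcome1 = outcome1, outcome2 = outcome2,
         predictors1 = as.character(predictors1),
         predictors2 = as.character(predictors2),
         cluster = cluster,
         categories1 = categories1, categories2 = categories2,
         ref1 = ref1, ref2 = ref2,
         references = refs),
    class = "jb_spec")
}

# Reference levels of the study's binary predictors (the level coded 0).
#' @noRd
default_reference_levels <- function() {
  list(
    preeclampsia        = "No",
    art                 = "No",
    multiple_pregnancy  = "No",
    stillbirth_history  = "No",
    abortion_history    = "No",
    infant_sex          = "Female",
    mother_education    = "Undergraduate",
    father_education    = "Undergraduate",
    mother_occupation   = "Housewife",
    pregnancy_type      = "Wanted",
    parity              = "1"
  )
}

#' The default joint model of the perinatal analysis
#'
#' The multivariable model the screening stage feeds: gestational-age class
#' on mother's age, socioeconomic status, mother's education, preeclampsia,
#' assisted reproduction and multiple pregnancy; birth-weight class on
#' mother's age, BMI, mother's education, stillbirth history, multiple
#' pregnancy, preeclampsia and infant sex.
#'
#' @return A `jb_spec`.
#' @export
default_spec <- function() {
  joint_spec(
    predictors1 = c("mother_age", "ses", "mother_education",
                    "preeclampsia", "art", "multiple_pregnancy"),
    predictors2 = c("mother_age", "bmi", "mother_education",
                    "stillbirth_history", "multiple_pregnancy",
                    "preeclampsia", "infant_sex"))
}

#' @export
print.jb_spec <- function(x, ...) {
  cat("<jb_spec>\n")
  cat(sprintf("  outcome 1: %s (%s; ref %s)\n", x$outcome1,
              paste(x$categories1, collapse = "/"), x$ref1))
  cat(sprintf("  outcome 2: %s (%s; ref %s)\n", x$outcome2,
              paste(x$categories2, collapse = "/"), x$ref2))
  cat(sprintf("  cluster:   %s\n", x$cluster))
  cat(sprintf("  predictors 1: %s\n",
              if (length(x$predictors1)) paste(x$predictors1, collapse = ", ") else "(none)"))
  cat(sprintf("  predictors 2: %s\n",
              if (length(x$predictors2)) paste(x$predictors2, collapse = ", ") else "(none)"))
  invisible(x)
}

# code one predictor column to numeric; binary factors -> 0/1 against the
# declared reference level
#' @noRd
code_predictor <- function(x, name, refs) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) == 0)
    abort(sprintf("Column `%s` has no non-missing values.", name))
  if (length(lev) > 2)
    abort(sprintf("Categorical predictor `%s` has %d levels; only binary predictors are supported.",
                  name, length(lev)))
  ref <- refs[[name]]
  if (is.null(ref)) {
    # fall back: "No"-like labels first, else alphabetical first level
    ref <- if ("No" %in% lev) "No" else lev[1]
  }
  if (!ref %in% lev && length(lev) == 2)
    abort(sprintf("Reference level '%s' for `%s` not found (levels: %s).",
                  ref, name, paste(lev, collapse = ", ")))
  out <- ifelse(x == ref, 0, 1)
  bad <- which(!x %in% lev)
  if (length(bad))
    abort(sprintf("Unknown label in column `%s` at row %d.", name, bad[1]))
  out
}

#' @noRd
code_outcome <- function(x, name, categories, ref) {
  x <- as.character(x)
  bad <- which(!is.na(x) & !x %in% categories)
  if (length(bad))
    abort(sprintf("Unknown category '%s' in outcome `%s` at row %d.",
                  x[bad[1]], name, bad[1]))
  nonref <- setdiff(categories, ref)
  y <- integer(length(x))
  y[is.na(x)] <- NA_integer_
  y[x == ref] <- 0L
  y[x == nonref[1]] <- 1L
  y[x == nonref[2]] <- 2L
  y
}

#' Build the coded design for a joint fit
#'
#' Validates the raw table against a model specification, codes binary
#' predictors 0/1 against their declared reference levels, maps the two
#' outcomes to category indices, drops incomplete rows (complete-case
#' analysis, with a message stating the count) and orders rows by cluster.
#'
#' @param data A data frame with one row per subject.
#' @param spec A [joint_spec()].
#' @param require_outcomes If `FALSE`, the outcome columns may be absent
#'   (used when coding covariate tables for simulation).
#' @return An object of class `jb_data`: the cleaned tibble plus coded
#'   outcome vectors, design matrices and the cluster index.
#' @export
build_design <- function(data, spec = default_spec(), require_outcomes = TRUE) {
  stopifnot(inherits(spec, "jb_spec"))
  data <- tibble::as_tibble(data)
  needed <- unique(c(spec$cluster,
                     if (require_outcomes) c(spec$outcome1, spec$outcome2),
                     spec$predictors1, spec$predictors2))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))

  for (nm in needed) {
    if (nrow(data) > 0 && all(is.na(data[[nm]])))
      abort(sprintf("Column `%s` is entirely missing.", nm))
  }

  preds <- unique(c(spec$predictors1, spec$predictors2))
  coded <- lapply(preds, function(nm)
    code_predictor(data[[nm]], nm, spec$references))
  names(coded) <- preds

  has_out <- require_outcomes ||
    all(c(spec$outcome1, spec$outcome2) %in% names(data))
  y1 <- y2 <- NULL
  if (has_out) {
    y1 <- code_outcome(data[[spec$outcome1]], spec$outcome1,
                       spec$categories1, spec$ref1)
    y2 <- code_outcome(data[[spec$outcome2]], spec$outcome2,
                       spec$categories2, spec$ref2)
  }

  keep <- !is.na(data[[spec$cluster]])
  for (v in coded) keep <- keep & !is.na(v)
  if (has_out) keep <- keep & !is.na(y1) & !is.na(y2)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    inform(sprintf("build_design: dropped %d incomplete row%s (complete-case).",
                   n_dropped, if (n_dropped == 1) "" else "s"))

  cl_raw <- data[[spec$cluster]][keep]
  ord <- order(match(cl_raw, unique(cl_raw)))
  cl <- as.integer(factor(cl_raw, levels = unique(cl_raw)))[ord]

  Xall <- if (length(preds))
    do.call(cbind, lapply(coded, function(v) v[keep][ord]))
  else matrix(0, sum(keep), 0)
  colnames(Xall) <- preds
  X1 <- Xall[, spec$predictors1, drop = FALSE]
  X2 <- Xall[, spec$predictors2, drop = FALSE]

  structure(
    list(data = data[keep, , drop = FALSE][ord, , drop = FALSE],
         y1 = if (has_out) y1[keep][ord] else NULL,
         y2 = if (has_out) y2[keep][ord] else NULL,
         X1 = X1, X2 = X2,
         cluster = cl,
         cluster_labels = as.character(unique(cl_raw)),
         n_dropped = n_dropped,
         spec = spec),
    class = "jb_data")
}

#' @export
print.jb_data <- function(x, ...) {
  cat(sprintf("<jb_data> %d subjects in %d clusters (%d dropped)\n",
              nrow(x$data), length(unique(x$cluster)), x$n_dropped))
  cat(sprintf("  sub-model 1: %d predictor(s); sub-model 2: %d predictor(s)\n",
              ncol(x$X1), ncol(x$X2)))
  invisible(x)
}

# cluster offsets (0-based, ncl + 1) for the compiled kernel; rows must be
# sorted by cluster, which build_design guarantees
#' @noRd
cluster_offsets <- function(cl) {
  stopifnot(!is.unsorted(cl))
  c(0L, cumsum(tabulate(cl)))
}
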