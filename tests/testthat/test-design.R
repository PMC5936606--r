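test_that("binary predictors are coded against their declared reference levels", {
  d <- tibble::tibble(
    hospital = c("A", "A", "B", "B"),
    gestational_age = factor(c("term", "preterm", "term", "postterm"),
                             levels = c("preterm", "term", "postterm")),
    birth_weight = factor(c("normal", "LBW", "macrosomia", "normal"),
                          levels = c("LBW", "normal", "macrosomia")),
    preeclampsia = c("Yes", "No", "No", "Yes"),
    infant_sex = c("Male", "Female", "Female", "Male"),
    mother_education = c("Graduate", "Undergraduate", "Graduate",
                         "Undergraduate"))
  spec <- joint_spec(predictors1 = c("preeclampsia", "infant_sex"),
                     predictors2 = "mother_education")
  jbd <- build_design(d, spec)
  expect_equal(unname(jbd$X1[, "preeclampsia"]), c(1, 0, 0, 1))
  expect_equal(unname(jbd$X1[, "infant_sex"]), c(1, 0, 0, 1))
  expect_equal(unname(jbd$X2[, "mother_education"]), c(1, 0, 1, 0))
  # outcome coding: reference category 0, non-reference in listed order
  expect_equal(jbd$y1, c(0L, 1L, 0L, 2L))
  expect_equal(jbd$y2, c(0L, 1L, 2L, 0L))
})

test_that("bad inputs fail loudly with location information", {
  d <- tibble::tibble(
    hospital = c("A", "B"),
    gestational_age = c("term", "term"),
    birth_weight = c("normal", "normal"),
    preeclampsia = c("Yes", "Maybe"))
  spec <- joint_spec(predictors1 = "preeclampsia")
  expect_error(build_design(d, spec), "Reference level.*preeclampsia")
  d3lev <- d
  d3lev$preeclampsia <- c("No", "Yes")
  d3lev <- dplyr::bind_rows(d3lev, dplyr::mutate(d3lev[1, ],
                                                 preeclampsia = "Odd"))
  expect_error(build_design(d3lev, spec), "preeclampsia.*3 levels")
  d2 <- d; d2$preeclampsia <- NA_character_
  expect_error(build_design(d2, spec), "entirely missing")
  d3 <- d; d3$gestational_age[2] <- "weird"
  d3$preeclampsia <- c("No", "Yes")
  expect_error(build_design(d3, spec), "weird")
  expect_error(build_design(d[, -1], spec), "hospital")
})

test_that("incomplete rows are dropped as complete cases with a count message", {
  tr <- xtruth(c(-1, -2), c(-1, -2))
  coh <- sim_xcohort(3, 10, tr, seed = 1)
  coh$x[c(2, 5)] <- NA
  expect_message(jbd <- build_design(coh, tr$spec), "dropped 2")
  expect_equal(nrow(jbd$data), 28)
  expect_equal(jbd$n_dropped, 2)
})

test_that("degenerate and collinear designs are rejected with column names", {
  tr <- xtruth(c(-1, -2), c(-1, -2))
  coh <- sim_xcohort(4, 10, tr, seed = 2)
  coh$x <- 0
  expect_error(fit_joint(coh, tr$spec), "Constant.*x")
  coh2 <- sim_xcohort(4, 10, tr, seed = 3)
  coh2$z <- coh2$x
  spec2 <- joint_spec(predictors1 = c("x", "z"), predictors2 = "x")
  expect_error(fit_joint(coh2, spec2), "collinear.*z")
})

test_that("estimates are invariant to row order and cluster relabeling", {
  tr <- xtruth(c(-1.2, -2.2), c(-1.5, -1.8), a_pre = 0.8, rho = 0.3)
  coh <- sim_xcohort(8, 25, tr, seed = 9)
  ctrl <- jb_control(n_starts = 1)
  f1 <- fit_joint(coh, tr$spec, ctrl)
  withr::with_seed(4, {
    perm <- sample(nrow(coh))
  })
  coh2 <- coh[perm, ]
  coh2$hospital <- factor(paste0("site-", coh2$hospital))
  f2 <- fit_joint(coh2, tr$spec, ctrl)
  expect_lt(max(abs(f1$psi - f2$psi)), 1e-8)
})
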