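test_that("crosstab partitions the data with consistent totals", {
  d <- tibble::tibble(
    a = factor(c("x", "x", "y"), levels = c("x", "y")),
    b = factor(c("p", "q", "q"), levels = c("p", "q")))
  xt <- crosstab(d, a, b)
  expect_equal(sum(xt$counts), 3)
  expect_equal(xt$counts["x", "p"], 1L)
  expect_equal(unname(rowSums(xt$counts)), c(2, 1))
  # empty data with declared levels -> all-zero table
  xt0 <- crosstab(d[0, ], a, b)
  expect_true(all(xt0$counts == 0))
  expect_equal(dim(xt0$counts), c(2, 2))
  # single row -> single unit cell
  xt1 <- crosstab(d[1, ], a, b)
  expect_equal(sum(xt1$counts), 1)
  expect_error(crosstab(tibble::tibble(a = 1:3, b = c("u", "v", "u")), a, b),
               "categorical")
})

test_that("the published outcome cross-tab reproduces its chi-square exactly", {
  xt <- published_outcome_crosstab()
  expect_equal(sum(xt$counts), 4415)
  res <- chisq_pearson(xt)
  expect_equal(round(res$statistic, 3), 940.308)
  expect_equal(res$df, 4L)
  expect_lt(res$p.value, 0.001)
})

test_that("Pearson statistic matches hand computation and is permutation-invariant", {
  m <- matrix(c(10, 0, 0, 10), 2)
  res <- chisq_pearson(m)
  expect_equal(res$statistic, 20)     # all expected counts are 5
  expect_equal(res$df, 1L)
  # independence table gives exactly zero
  ind <- outer(c(4, 6), c(10, 30)) / 10
  expect_equal(chisq_pearson(ind)$statistic, 0)
  # invariance to permutation and transposition
  xt <- published_outcome_crosstab()$counts
  expect_equal(chisq_pearson(xt[c(3, 1, 2), c(2, 3, 1)])$statistic,
               chisq_pearson(xt)$statistic)
  expect_equal(chisq_pearson(t(xt))$statistic, chisq_pearson(xt)$statistic)
})

test_that("zero-margin rows/columns are dropped with df adjustment", {
  m <- rbind(c(5, 10), c(0, 0), c(8, 2))
  expect_warning(res <- chisq_pearson(m), "zero-margin")
  expect_equal(res$df, 1L)
  expect_error(chisq_pearson(matrix(0, 2, 2)), "no observations")
})

test_that("prevalences reproduce the published rates from printed group sizes", {
  gs <- published_group_sizes()
  for (oc in unique(gs$outcome)) {
    sub <- gs[gs$outcome == oc, ]
    d <- tibble::tibble(y = factor(rep(sub$category, sub$n),
                                   levels = sub$category))
    pv <- prevalence(d, y)
    expect_equal(pv$n, sub$n)
    target <- if (oc == "gestational_age") c(5.5, 94.0, 0.5)
              else c(4.8, 92.4, 2.8)
    expect_equal(round(pv$percent, 1), target)
  }
  expect_equal(prevalence(tibble::tibble(y = rep("only", 5)), y)$percent, 100)
  expect_error(prevalence(tibble::tibble(y = NA_character_), y), "non-missing")
})

test_that("group summaries give ANOVA / chi-square tests with closed percentages", {
  withr::with_seed(6, {
    g <- rep(c("a", "b", "c"), each = 500)
    d <- tibble::tibble(
      grp = g,
      age = rnorm(1500, mean = ifelse(g == "a", 32, 30), sd = 5),
      flat = rnorm(1500),
      cat = sample(c("No", "Yes"), 1500, replace = TRUE))
  })
  gs <- group_summary(d, grp)
  tests <- gs$tests
  expect_lt(tests$p.value[tests$variable == "age"], 0.001)
  expect_gt(tests$p.value[tests$variable == "flat"], 0.001)
  expect_equal(tests$test[tests$variable == "cat"], "Pearson chi-square")
  # row percentages close to 100 within each categorical level
  sums <- tapply(gs$categorical$percent, gs$categorical$level, sum)
  expect_true(all(abs(sums - 100) < 0.2))
  # per-group means carry the shift
  cont <- gs$continuous
  expect_gt(cont$mean[cont$variable == "age" & cont$group == "a"],
            cont$mean[cont$variable == "age" & cont$group == "b"] + 1)
  expect_warning(group_summary(
    tibble::tibble(grp = factor(c("a", "a"), levels = c("a", "b")),
                   v = c(1, 2)), grp), "Empty group")
})
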