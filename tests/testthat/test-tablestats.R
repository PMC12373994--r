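test_that("summary-statistic tests match stats:: on exact-moment raw data", {
  # raw vectors constructed to carry exactly the summary moments let the
  # base-R tests act as an independent oracle for the summary formulas
  a <- raw_with_moments(24, 5.29, 3.3)
  b <- raw_with_moments(11, 27.64, 32.5)
  ours <- welch_t(group_summary("TC", 24, 5.29, 3.3),
                  group_summary("PTSD", 11, 27.64, 32.5))
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)

  g <- list(group_summary("HC", 16, 29.37, 8.16),
            group_summary("TC", 27, 45.78, 13.90),
            group_summary("PTSD", 19, 42.58, 13.03))
  raw <- data.frame(
    y = c(raw_with_moments(16, 29.37, 8.16),
          raw_with_moments(27, 45.78, 13.90),
          raw_with_moments(19, 42.58, 13.03)),
    grp = rep(c("HC", "TC", "PTSD"), c(16, 27, 19)))
  ref_f <- summary(aov(y ~ grp, data = raw))[[1]]$`F value`[1]
  expect_equal(anova_f(g)$F, ref_f, tolerance = 1e-10)

  counts <- matrix(c(9, 25, 10, 7, 2, 9), ncol = 2,
                   dimnames = list(c("HC", "TC", "PTSD"), c("yes", "no")))
  ref_c <- suppressWarnings(chisq.test(counts, correct = FALSE))
  expect_equal(pearson_chi2(counts)$chisq, unname(ref_c$statistic),
               tolerance = 1e-10)
  expect_equal(pearson_chi2(counts)$df, unname(ref_c$parameter))
})

test_that("published trauma-history t statistics reproduce under Welch", {
  r1 <- welch_t(group_summary("TC", 24, 5.29, 3.3),
                group_summary("PTSD", 11, 27.64, 32.5))
  expect_lt(abs(abs(r1$t) - 2.27), 0.02)
  expect_equal(round(r1$df), 10)
  r2 <- welch_t(group_summary("TC", 21, 16.52, 7.1),
                group_summary("PTSD", 10, 14.3, 7.96))
  expect_lt(abs(abs(r2$t) - 0.75), 0.02)
  expect_equal(round(r2$df), 16)
})

test_that("published ANOVA and chi-squared statistics reproduce", {
  f_age <- anova_f(list(group_summary("HC", 16, 29.37, 8.16),
                        group_summary("TC", 27, 45.78, 13.90),
                        group_summary("PTSD", 19, 42.58, 13.03)))
  expect_lt(abs(f_age$F - 9.14), max(0.02, 0.01 * 9.14))
  expect_equal(c(f_age$df_between, f_age$df_within), c(2, 59))
  f_bmi <- anova_f(list(group_summary("HC", 16, 25.76, 4.88),
                        group_summary("TC", 27, 29.74, 6.04),
                        group_summary("PTSD", 19, 30.133, 5.79)))
  expect_lt(abs(f_bmi$F - 3.17), max(0.02, 0.01 * 3.17))

  sex <- matrix(c(9, 25, 10, 7, 2, 9), ncol = 2)
  x_sex <- pearson_chi2(sex)
  expect_lt(abs(x_sex$chisq - 10.91), max(0.02, 0.01 * 10.91))
  expect_equal(x_sex$df, 2)
  vet <- matrix(c(0, 24, 11, 16, 3, 8), ncol = 2)
  expect_lt(abs(pearson_chi2(vet)$chisq - 32.31), max(0.02, 0.01 * 32.31))
})

test_that("algebraic identities hold", {
  # two-group ANOVA F equals the squared pooled-variance t
  a <- group_summary("x", 12, 10, 2); b <- group_summary("y", 15, 11.5, 2.4)
  f2 <- anova_f(list(a, b))$F
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  t_pooled <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  expect_equal(f2, t_pooled^2, tolerance = 1e-12)
  # Welch t antisymmetry
  w <- welch_t(a, b)
  w_swap <- welch_t(b, a)
  expect_equal(w$t, -w_swap$t)
  expect_equal(w$df, w_swap$df)
  # chi-squared permutation invariance
  m <- matrix(c(3, 8, 5, 9, 2, 7), 3, 2)
  expect_equal(pearson_chi2(m)$chisq, pearson_chi2(m[c(2, 3, 1), ])$chisq)
  expect_equal(pearson_chi2(m)$chisq, pearson_chi2(m[, 2:1])$chisq)
  # degenerate inputs
  expect_equal(anova_f(list(a, group_summary("z", 10, 10, 3)))$F, 0)
  expect_equal(welch_t(a, a)$t, 0)
  expect_error(group_summary("x", 1, 0, 1), "n >= 2")
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("cohort-table checks pass for every reproducible row", {
  checks <- cohort_table_checks()
  expect_equal(nrow(checks), 6)
  expect_true(all(checks$pass))
  all_rows <- cohort_table_checks(include_nonreproducible = TRUE)
  expect_equal(nrow(all_rows), 10)
  expect_true(all(is.na(all_rows$pass[!all_rows$variable %in% checks$variable])))
})
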