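test_that("group recipe builds the eight-column dummy-interaction design", {
  ch <- generate_cohort(cohort_config(), seed = 5)
  d <- build_design(ch, "group", region = "whole_brain")
  expect_equal(d$coef_names, c("intercept", "tc", "ptsd", "sex", "age_z",
                               "bmi_z", "tc_sex", "ptsd_sex"))
  expect_equal(nrow(d$X), 62)
  # HC males are the reference: their rows are zero outside the intercept
  hc_male <- ch$group == "HC" & ch$sex == "male"
  expect_true(all(d$X[hc_male, -c(1, 5, 6)] == 0))
  # z-scored covariates
  expect_lt(abs(mean(d$X[, "age_z"])), 1e-12)
  expect_lt(abs(sd(d$X[, "age_z"]) - 1), 1e-12)
  expect_lt(abs(mean(d$X[, "bmi_z"])), 1e-12)
})

test_that("symptom recipe restricts to trauma-exposed subjects with CAPS", {
  ch <- generate_cohort(cohort_config(), seed = 5)
  d <- build_design(ch, "symptom", cluster = "c8_anhedonia")
  expect_equal(nrow(d$X), 46)  # 27 TC + 19 PTSD
  expect_equal(d$coef_names[2], "c8_anhedonia")
  # raw (unstandardized) cluster scores enter the design
  expect_equal(unname(d$X[, 2]),
               ch$c8_anhedonia[ch$group %in% c("TC", "PTSD")])
  # a missing CAPS drops the subject with a log message
  ch2 <- ch
  ch2$c8_anhedonia[ch2$group == "TC"][1] <- NA
  expect_message(d2 <- build_design(ch2, "symptom", cluster = "c8_anhedonia"),
                 "dropped")
  expect_equal(nrow(d2$X), 45)
})

test_that("degenerate designs are rejected", {
  ch <- generate_cohort(cohort_config(n_ptsd = 0, n_tc = 0, n_hc = 12,
                                      p_male = c(hc = 1, tc = 1, ptsd = 1)),
                        seed = 2)
  expect_error(build_design(ch, "group"), "group recipe|variation")
  ch3 <- generate_cohort(cohort_config(), seed = 5)
  ch3$age <- 40
  expect_error(build_design(ch3, "confounds"), "zero-variance")
})

test_that("HPD interval matches closed-form and brute-force oracles", {
  expect_equal(diff(hpd_interval(1:100, 0.89)), 88)
  set.seed(123)
  z <- rnorm(1e5)
  h <- hpd_interval(z, 0.89)
  expect_lt(abs(h[1] + 1.60), 0.05)
  expect_lt(abs(h[2] - 1.60), 0.05)
  expect_equal(hpd_interval(rep(3.3, 200)), c(3.3, 3.3))
  expect_error(hpd_interval(rnorm(50)), "at least 100")
  # minimal-width property against exhaustive window scan, skewed samples
  set.seed(7)
  for (i in 1:10) {
    s <- rgamma(300 + 10 * i, shape = 1.3)
    for (mass in c(0.5, 0.89, 0.95)) {
      got <- hpd_interval(s, mass)
      oracle <- hpd_bruteforce(s, mass)
      expect_equal(got, oracle)
      expect_gte(mean(s >= got[1] & s <= got[2]), mass)
    }
  }
})

test_that("split-Rhat and ESS behave like the standard diagnostics", {
  set.seed(42)
  # well-mixed iid chains: Rhat near 1, ESS near total draws
  m <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(m), 1.01)
  expect_gt(ess_bulk(m), 2500)
  # separated chains: Rhat far above threshold, ESS collapses
  m2 <- m; m2[, 1] <- m2[, 1] + 5
  expect_gt(split_rhat(m2), 1.2)
  # strong AR(1): ESS shrinks roughly like coda's estimate
  ar <- replicate(4, as.numeric(arima.sim(list(ar = 0.9), 1000)))
  ours <- ess_bulk(ar)
  coda_est <- sum(apply(ar, 2, function(x) coda::effectiveSize(coda::mcmc(x))))
  expect_lt(ours, 1500)
  expect_lt(abs(log(ours / coda_est)), log(2.5))  # same order of magnitude
})

test_that("robustness flag is exactly the HPD-excludes-zero rule", {
  ch <- generate_cohort(cohort_config(), seed = 13)
  d <- build_design(ch, "confounds")
  fit <- suppressWarnings(fit_model(d, seed = 13))
  cf <- fit$coefficients
  expect_equal(cf$robust, cf$hpd_low > 0 | cf$hpd_high < 0)
  expect_true(all(cf$hpd_low < cf$hpd_high))
})

test_that("shifting the outcome shifts only the intercept posterior", {
  ch <- generate_cohort(cohort_config(effect_sizes = c()), seed = 17)
  d <- build_design(ch, "confounds")
  f0 <- suppressWarnings(fit_model(d, seed = 17))
  d1 <- d; d1$y <- d$y + 0.5
  f1 <- suppressWarnings(fit_model(d1, seed = 17))
  i0 <- f0$coefficients[1, ]; i1 <- f1$coefficients[1, ]
  expect_lt(abs((i1$mean - i0$mean) - 0.5), 3 * i0$sd)
  for (j in 2:4)
    expect_lt(abs(f1$coefficients$mean[j] - f0$coefficients$mean[j]),
              3 * f0$coefficients$sd[j])
})

test_that("Student-t regression resists gross outliers better than OLS", {
  set.seed(101)
  errs <- t(vapply(1:50, function(s) {
    set.seed(1000 + s)
    n <- 62
    x <- rnorm(n)
    y <- 0.2 + 0.5 * x + rnorm(n, 0, 0.3)
    out <- sample(n, 3)  # ~5% gross outliers
    y[out] <- y[out] + sample(c(-1, 1), 3, TRUE) * runif(3, 3, 6)
    d <- list(X = cbind(intercept = 1, x = x), y = y,
              coef_names = c("intercept", "x"))
    bfit <- suppressWarnings(fit_model(d, draws = 500, tune = 500,
                                       chains = 2, seed = s))
    c(bayes = abs(bfit$coefficients$mean[2] - 0.5),
      ols = abs(coef(lm(y ~ x))[[2]] - 0.5))
  }, numeric(2)))
  expect_lt(mean(errs[, "bayes"]), mean(errs[, "ols"]))
})

test_that("under-sampled chains fail the convergence gate", {
  ch <- generate_cohort(cohort_config(), seed = 23)
  d <- build_design(ch, "confounds")
  expect_warning(short <- fit_model(d, draws = 60, tune = 100, chains = 2,
                                    seed = 23),
                 "convergence gate")
  expect_false(short$converged)  # 120 total draws can never reach ESS > 1000
  expect_true(all(short$coefficients$ess <= 1000))
})

test_that("model suite emits the three report tables and survives failures", {
  ch <- generate_cohort(cohort_config(), seed = 29)
  suite <- run_model_suite(ch, regions = "whole_brain",
                           draws = 300, tune = 300, chains = 2, seed = 29)
  expect_equal(nrow(suite$confounds), 3)
  expect_equal(suite$confounds$measure, c("Sex", "Age", "BMI"))
  expect_equal(nrow(suite$group), 4)
  expect_equal(nrow(suite$symptom), 13)
  expect_equal(suite$symptom$measure, names(symptom_model_set()))
  expect_false(any(suite$symptom$failed))
  # PTSD+TC-only cohort: group family fails gracefully, symptom family runs
  ch2 <- generate_cohort(cohort_config(n_hc = 0), seed = 31)
  expect_message(
    suite2 <- run_model_suite(ch2, regions = "whole_brain",
                              draws = 300, tune = 300, chains = 2, seed = 31),
    "group model failed")
  expect_true(all(suite2$group$failed))
  expect_false(any(suite2$symptom$failed))
})
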