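test_that("MA1 recovers one- and two-tissue V_T on noiseless TACs", {
  tac1 <- simulate_tac(kinetic_params(0.1, 0.1), fx_input, fx_schedule)
  est1 <- ma1_vt(tac1, fx_input)
  expect_lt(abs(est1$vt - 1.0), 0.01)
  expect_true(est1$valid)
  expect_gte(est1$n_frames_used, 3)

  tac2 <- simulate_tac(kinetic_params(0.3, 0.15, 0.05, 0.05), fx_input,
                       fx_schedule)
  est2 <- ma1_vt(tac2, fx_input)
  expect_lt(abs(est2$vt - 4.0) / 4.0, 0.01)
})

test_that("Logan agrees with MA1 and the analytic value on noiseless TACs", {
  tac <- simulate_tac(kinetic_params(0.3, 0.15, 0.05, 0.05), fx_input,
                      fx_schedule)
  lg <- logan_vt(tac, fx_input)
  ma <- ma1_vt(tac, fx_input)
  expect_lt(abs(lg$vt - ma$vt) / ma$vt, 0.02)
  expect_lt(abs(lg$vt - 4.0) / 4.0, 0.02)
  tac1 <- simulate_tac(kinetic_params(0.1, 0.1), fx_input, fx_schedule)
  expect_lt(abs(logan_vt(tac1, fx_input)$vt - 1.0), 0.01)
})

test_that("degenerate and underdetermined fits raise errors", {
  zero_tac <- simulate_tac(kinetic_params(0, 0.1), fx_input, fx_schedule)
  expect_error(logan_vt(zero_tac, fx_input), "degenerate")
  tac <- simulate_tac(kinetic_params(0.3, 0.15, 0.05, 0.05), fx_input,
                      fx_schedule)
  expect_error(ma1_vt(tac, fx_input, t_star = 115), "insufficient frames")
})

test_that("MA1 is scale equivariant", {
  tac <- simulate_tac(kinetic_params(0.3, 0.15, 0.05, 0.05), fx_input,
                      fx_schedule)
  ref <- ma1_vt(tac, fx_input)$vt
  tac3 <- tac; tac3$activity <- tac3$activity * 3
  inp3 <- input_function(fx_input$time, fx_input$conc * 3)
  expect_lt(abs(ma1_vt(tac3, inp3)$vt - ref), 1e-6)      # both scaled
  expect_lt(abs(ma1_vt(tac, inp3)$vt - ref / 3), 1e-6)   # input only
})

test_that("V_T is insensitive to the t* choice for reversible kinetics", {
  tac <- simulate_tac(kinetic_params(0.3, 0.15, 0.05, 0.05), fx_input,
                      fx_schedule)
  v30 <- ma1_vt(tac, fx_input, t_star = 30)$vt
  v40 <- ma1_vt(tac, fx_input, t_star = 40)$vt
  expect_lt(abs(v30 - v40) / v30, 0.02)
})

test_that("MA1 bias stays small under frame-count noise", {
  kp <- kinetic_params_for_vt(4.0)
  ests <- vapply(1:100, function(s) {
    tac <- simulate_tac(kp, fx_input, fx_schedule, noise_scale = 0.05,
                        seed = 4000 + s)
    ma1_vt(tac, fx_input)$vt
  }, numeric(1))
  expect_lt(abs(mean(ests) - 4.0) / 4.0, 0.05)
})

test_that("whole-brain composite is the weighted mean of valid regions", {
  mk <- function(region, vt) {
    e <- list(region = region, vt = vt, b = 1, n_frames_used = 10,
              condition_number = 1, residual_rms = 0, valid = vt > 0,
              method = "MA1")
    class(e) <- "vt_estimate"
    e
  }
  regions <- c("frontal", "temporal", "parietal", "occipital", "cerebellum")
  # constant invariance
  ests <- lapply(regions, mk, vt = 1.2)
  expect_equal(composite_whole_brain(ests, aal_lobe_weights()), 1.2)
  # two-region weighted mean
  expect_equal(composite_whole_brain(list(mk("a", 1), mk("b", 2)),
                                     c(a = 1, b = 3)), 1.75)
  # brute-force oracle on random inputs
  set.seed(99)
  for (i in 1:5) {
    vt <- runif(5, 0.5, 3)
    w <- setNames(runif(5, 0.1, 2), regions)
    got <- composite_whole_brain(mapply(mk, regions, vt, SIMPLIFY = FALSE), w)
    expect_equal(got, sum(w * vt) / sum(w), tolerance = 1e-12)
  }
  # invalid estimates are excluded; all-invalid errors; weight mismatch errors
  ests2 <- list(mk("a", 1.5), mk("b", -0.2))
  expect_equal(composite_whole_brain(ests2, c(a = 2)), 1.5)
  expect_error(composite_whole_brain(list(mk("a", -1)), c(a = 1)), "empty")
  expect_error(composite_whole_brain(ests2, c(a = 1, b = 1)), "exactly")
})
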