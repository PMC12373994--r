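# Shared fixtures, computed once per test run.

fx_model <- input_function_model()
fx_input <- sample_input_function(fx_model)
fx_schedule <- frame_schedule()

# degenerate parent-fraction "fit" holding p = p_inf at every positive time
constant_pf_fit <- function(p_inf) {
  structure(list(p_inf = p_inf, alpha = 1, theta = 1e-9,
                 fit_residual_rms = 0, method = "gamma_survival"),
            class = "parent_fraction_fit")
}

# raw data vector with exactly the requested mean and sd (for cross-checking
# summary-statistic formulas against stats:: tests on raw data)
raw_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  mean + sd * (x - mean(x)) / stats::sd(x)
}

# brute-force shortest window containing >= ceiling(mass*n) sorted samples
hpd_bruteforce <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + m - 1])
  }
  best
}
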