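#' Arterial input-function model for the simulator
#'
#' Parametric ground truth for arterial blood: total plasma activity follows
#' a Feng-type curve (linear upslope into a tri-exponential decay),
#' \deqn{C_p(t) = (A_1 u - A_2 - A_3) e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u}
#'       + A_3 e^{-\lambda_3 u}, \quad u = t - delay,}
#' zero before the delay; the unmetabolized parent fraction decays from 1
#' as the survival function of a gamma law,
#' \deqn{p(t) = p_\infty + (1 - p_\infty) Q(\alpha, t/\theta),}
#' and whole-blood activity is plasma divided by a constant
#' plasma-to-whole-blood ratio. The metabolite-corrected input that drives
#' tissue kinetics is \eqn{C_p(t) \, p(t)}.
#'
#' @param A Amplitudes \code{c(A1, A2, A3)}; A1 in kBq/mL/min, A2, A3 in
#'   kBq/mL.
#' @param lambda Rate constants \code{c(l1, l2, l3)} in 1/min, l1 > l2 > l3.
#' @param delay Appearance delay (min).
#' @param pf Parent-fraction parameters \code{c(p_inf, alpha, theta)}:
#'   terminal fraction in [0,1], gamma shape > 0, gamma scale (min) > 0.
#' @param plasma_to_wholeblood Constant plasma/whole-blood activity ratio.
#' @return Object of class \code{input_function_model}.
#' @export
input_function_model <- function(A = c(300, 15, 12),
                                 lambda = c(3.5, 0.12, 0.012),
                                 delay = 0.5,
                                 pf = c(p_inf = 0.1, alpha = 1.5, theta = 20),
                                 plasma_to_wholeblood = 1.6) {
  if (length(A) != 3 || length(lambda) != 3)
    stop("A and lambda must each have length 3", call. = FALSE)
  if (any(lambda <= 0) || delay < 0)
    stop("rate constants must be positive and delay non-negative", call. = FALSE)
  pf <- stats::setNames(as.numeric(pf), c("p_inf", "alpha", "theta"))
  if (pf["p_inf"] < 0 || pf["p_inf"] > 1 || pf["alpha"] <= 0 || pf["theta"] <= 0)
    stop("parent-fraction parameters out of range", call. = FALSE)
  if (plasma_to_wholeblood <= 0)
    stop("plasma_to_wholeblood must be positive", call. = FALSE)
  structure(list(A = A, lambda = lambda, delay = delay, pf = pf,
                 plasma_to_wholeblood = plasma_to_wholeblood),
            class = "input_function_model")
}

#' Total plasma activity of the simulator's arterial model
#' @param model An [input_function_model()].
#' @param t Times (min), vectorised.
#' @return kBq/mL, zero before the appearance delay.
#' @export
plasma_conc <- function(model, t) {
  u <- t - model$delay
  A <- model$A; l <- model$lambda
  out <- (A[1] * u - A[2] - A[3]) * exp(-l[1] * u) +
    A[2] * exp(-l[2] * u) + A[3] * exp(-l[3] * u)
  out[u < 0] <- 0
  pmax(out, 0)
}

#' Parent-fraction curve (gamma survival form)
#'
#' \eqn{p(t) = p_\infty + (1-p_\infty) Q(\alpha, t/\theta)} with Q the
#' regularized upper incomplete gamma function; p(0) = 1, monotone
#' non-increasing, asymptote \eqn{p_\infty}.
#'
#' @param t Times (min).
#' @param p_inf,alpha,theta Curve parameters.
#' @return Parent fraction in [0, 1].
#' @export
parent_fraction_curve <- function(t, p_inf, alpha, theta) {
  p_inf + (1 - p_inf) * stats::pgamma(t / theta, shape = alpha,
                                      lower.tail = FALSE)
}

#' Metabolite-corrected plasma concentration (simulator truth)
#' @inheritParams plasma_conc
#' @return kBq/mL: total plasma times parent fraction.
#' @export
corrected_plasma_conc <- function(model, t) {
  p <- parent_fraction_curve(t, model$pf["p_inf"], model$pf["alpha"],
                             model$pf["theta"])
  plasma_conc(model, t) * p
}

#' Tabulate the true corrected input on a dense grid
#'
#' Builds an [input_function()] from the model's corrected plasma curve so
#' kinetic estimators can consume the exact simulator truth.
#'
#' @param model An [input_function_model()].
#' @param t_end End of the grid (min).
#' @param by_early,by_late Grid spacing before/after 10 min.
#' @return An \code{input_function}.
#' @export
sample_input_function <- function(model, t_end = 120, by_early = 0.02,
                                  by_late = 0.25) {
  grid <- sort(unique(c(seq(0, min(10, t_end), by = by_early),
                        seq(0, t_end, by = by_late), t_end)))
  input_function(grid, corrected_plasma_conc(model, grid))
}

#' Default arterial sampling schedules
#'
#' Discrete draws at 3, 5, 7, 10, 15, 20, 30, 45, 60, 75, 90, 105 and
#' 120 min post-injection; HPLC parent-fraction measurements at 5, 15, 30,
#' 60, 90 and 120 min.
#' @return Named list with \code{draw_times} (13 values) and
#'   \code{hplc_times} (6 values), minutes.
#' @export
blood_sampling_schedule <- function() {
  list(draw_times = c(3, 5, 7, 10, 15, 20, 30, 45, 60, 75, 90, 105, 120),
       hplc_times = c(5, 15, 30, 60, 90, 120))
}

#' Simulate an arterial blood-sample table
#'
#' Emulates the blood-side measurements: an optional continuous whole-blood
#' segment over the first 7 min, discrete whole-blood/plasma draws, and
#' noisy parent-fraction determinations at the HPLC times (clipped to
#' [0, 1]).
#'
#' @param model An [input_function_model()].
#' @param draw_times Discrete sample times (min), within [0, 120].
#' @param hplc_times Parent-fraction measurement times (min).
#' @param continuous If TRUE, add a 5-s-resolution whole-blood segment over
#'   the first 7 min (plasma and parent fraction NA there).
#' @param noise Relative noise SD applied multiplicatively to activities and
#'   additively (absolute, same value) to parent fractions; 0 = noiseless.
#' @param seed Optional integer seed.
#' @return Data.frame of class \code{blood_samples}: \code{time_min},
#'   \code{wholeblood_kBq_mL}, \code{plasma_kBq_mL}, \code{parent_fraction},
#'   \code{source} ("continuous"/"discrete").
#' @export
simulate_blood <- function(model,
                           draw_times = blood_sampling_schedule()$draw_times,
                           hplc_times = blood_sampling_schedule()$hplc_times,
                           continuous = TRUE, noise = 0, seed = NULL) {
  if (any(draw_times < 0 | draw_times > 120))
    stop("draw times must lie within [0, 120] min", call. = FALSE)
  if (!all(hplc_times %in% draw_times))
    draw_times <- sort(unique(c(draw_times, hplc_times)))
  if (!is.null(seed)) set.seed(seed)

  mk <- function(times, src) {
    pl <- plasma_conc(model, times)
    wb <- pl / model$plasma_to_wholeblood
    data.frame(time_min = times, wholeblood_kBq_mL = wb,
               plasma_kBq_mL = if (src == "discrete") pl else NA_real_,
               parent_fraction = NA_real_, source = src,
               stringsAsFactors = FALSE)
  }
  tab <- mk(sort(draw_times), "discrete")
  if (continuous) {
    ct <- setdiff(seq(0, 7, by = 1 / 12), tab$time_min)
    tab <- rbind(mk(ct, "continuous"), tab)
    tab <- tab[order(tab$time_min), ]
  }
  idx <- match(hplc_times, tab$time_min)
  tab$parent_fraction[idx] <- parent_fraction_curve(
    hplc_times, model$pf["p_inf"], model$pf["alpha"], model$pf["theta"])

  if (noise > 0) {
    act <- tab$wholeblood_kBq_mL
    tab$wholeblood_kBq_mL <- pmax(act * (1 + stats::rnorm(length(act), 0, noise)), 0)
    ok <- !is.na(tab$plasma_kBq_mL)
    tab$plasma_kBq_mL[ok] <- pmax(tab$plasma_kBq_mL[ok] *
      (1 + stats::rnorm(sum(ok), 0, noise)), 0)
    pfok <- !is.na(tab$parent_fraction)
    tab$parent_fraction[pfok] <- pmin(pmax(tab$parent_fraction[pfok] +
      stats::rnorm(sum(pfok), 0, noise), 0), 1)
  }
  rownames(tab) <- NULL
  class(tab) <- c("blood_samples", "data.frame")
  tab
}
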