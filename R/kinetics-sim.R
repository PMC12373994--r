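#' Two-tissue-compartment kinetic parameters
#'
#' Rate constants of the reversible two-tissue compartment model used as the
#' simulator's ground truth: K1 (plasma-to-tissue delivery), k2 (efflux),
#' k3/k4 (exchange with the specifically bound pool) and vB (fractional
#' blood volume in the region).
#'
#' @param K1 mL cm^-3 min^-1, > 0.
#' @param k2 min^-1, > 0.
#' @param k3,k4 min^-1, >= 0; k3 > 0 requires k4 > 0 (reversible binding).
#' @param vB unitless blood-volume fraction in [0, 1).
#' @return Object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  if (K1 < 0 || k2 <= 0) stop("require K1 >= 0 and k2 > 0", call. = FALSE)
  if (k3 < 0 || k4 < 0) stop("k3 and k4 must be non-negative", call. = FALSE)
  if (k3 > 0 && k4 == 0)
    stop("k3 > 0 with k4 = 0: irreversible trapping has no finite V_T",
         call. = FALSE)
  if (vB < 0 || vB >= 1) stop("vB must lie in [0, 1)", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "kinetic_params")
}

#' Analytic volume of distribution of a two-tissue compartment model
#'
#' Closed-form equilibrium tissue:plasma concentration ratio,
#' \eqn{V_T = (K_1/k_2)(1 + k_3/k_4)}, reducing to \eqn{K_1/k_2} when
#' \eqn{k_3 = 0}. This is the simulator's ground truth against which the
#' MA1 and Logan estimators are validated.
#'
#' @param params A [kinetic_params()].
#' @return The volume of distribution (unitless volume ratio).
#' @export
analytic_vt <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  with(params, if (k3 == 0) K1 / k2 else (K1 / k2) * (1 + k3 / k4))
}

#' PET frame schedule
#'
#' Default: 33 frames spanning 0-120 min (6 x 30 s, 3 x 60 s, 2 x 120 s,
#' 22 x 300 s), the dynamic histogramming the quantification assumes.
#'
#' @param durations Frame durations in minutes, in order.
#' @param start Scan start time (min).
#' @return Data.frame with \code{frame_start}, \code{frame_end},
#'   \code{frame_mid}, \code{frame_dur} (min).
#' @export
frame_schedule <- function(durations = c(rep(0.5, 6), rep(1, 3), rep(2, 2),
                                         rep(5, 22)),
                           start = 0) {
  if (any(durations <= 0)) stop("frame durations must be positive", call. = FALSE)
  ends <- start + cumsum(durations)
  starts <- c(start, ends[-length(ends)])
  data.frame(frame_start = starts, frame_end = ends,
             frame_mid = (starts + ends) / 2, frame_dur = durations)
}

# Evaluate any supported input-function representation at times t.
eval_cp <- function(input_fn, t) {
  if (inherits(input_fn, "input_function")) eval_input(input_fn, t)
  else if (is.function(input_fn)) input_fn(t)
  else stop("input_fn must be an input_function or a function of time",
            call. = FALSE)
}

# Exact convolution of a piecewise-linear curve (tt, cp) with exp(-theta t):
# I(t_j) = int_0^{t_j} exp(-theta (t_j - s)) cp(s) ds, via the per-interval
# closed form and a forward recurrence (stable for any theta >= 0).
conv_exp <- function(theta, tt, cp) {
  n <- length(tt)
  h <- diff(tt)
  m <- diff(cp) / h
  if (theta > 0) {
    eh <- exp(-theta * h)
    A <- (1 - eh) / theta                  # int exp(-theta(h-s)) ds
    B <- h / theta - (1 - eh) / theta^2    # int s exp(-theta(h-s)) ds
  } else {
    eh <- rep(1, n - 1)
    A <- h
    B <- h^2 / 2
  }
  piece <- cp[-n] * A + m * B
  out <- numeric(n)
  for (j in seq_len(n - 1)) out[j + 1] <- out[j] * eh[j] + piece[j]
  out
}

# Tissue response C1 + C2 of the two-tissue model to the input sampled on a
# grid: bi-exponential impulse response convolved exactly with the
# piecewise-linear input.
tissue_response <- function(params, tt, cp) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3; k4 <- params$k4
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 0) disc <- 0  # cannot occur for non-negative rates; guard fp
  th1 <- (s + sqrt(disc)) / 2
  th2 <- (s - sqrt(disc)) / 2
  if (abs(th1 - th2) < 1e-12 * max(th1, 1)) {
    # critically damped corner case: split the roots infinitesimally
    th1 <- th1 * (1 + 1e-8); th2 <- th2 * (1 - 1e-8)
  }
  phi1 <- K1 * (th1 - k3 - k4) / (th1 - th2)
  phi2 <- K1 * (k3 + k4 - th2) / (th1 - th2)
  ct <- numeric(length(tt))
  if (abs(phi1) > 0) ct <- ct + phi1 * conv_exp(th1, tt, cp)
  if (abs(phi2) > 0) ct <- ct + phi2 * conv_exp(th2, tt, cp)
  if (any(!is.finite(ct)))
    stop("tissue kinetics produced non-finite values (K1=", K1, ", k2=", k2,
         ", k3=", k3, ", k4=", k4, ")", call. = FALSE)
  ct
}

#' Simulate a regional time-activity curve
#'
#' Solves the two-tissue compartment system
#' \deqn{dC_1/dt = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' driven by the metabolite-corrected plasma input (exactly, by convolving
#' the system's bi-exponential impulse response with the piecewise-linear
#' input), frame-averages the total
#' tissue signal \eqn{(1 - v_B)(C_1 + C_2) + v_B C_{wb}}, and adds optional
#' zero-mean Gaussian noise with SD
#' \code{noise_scale * sqrt(activity / frame_dur)}, so that relative noise
#' shrinks with longer frames, as for reconstructed PET counts.
#'
#' @param params [kinetic_params()].
#' @param input_fn Metabolite-corrected plasma input: an
#'   \code{input_function} object or a vectorised function of time (min ->
#'   kBq/mL).
#' @param schedule A [frame_schedule()].
#' @param noise_scale Unitless noise multiplier; 0 gives a deterministic TAC.
#' @param seed Optional integer seed for the noise draw.
#' @param region Region label attached to the output.
#' @param wholeblood_fn Whole-blood activity function, required when
#'   \code{vB > 0}.
#' @return Data.frame of class \code{tac}: \code{region},
#'   \code{frame_start}, \code{frame_end}, \code{activity} (kBq/mL).
#' @export
simulate_tac <- function(params, input_fn, schedule = frame_schedule(),
                         noise_scale = 0, seed = NULL, region = "region",
                         wholeblood_fn = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$vB > 0 && is.null(wholeblood_fn))
    stop("vB > 0 requires wholeblood_fn", call. = FALSE)
  t_end <- max(schedule$frame_end)

  # dense solution grid: fine early (bolus peak), coarser late, plus all
  # frame boundaries so frame averages use exact edges
  grid <- sort(unique(c(seq(0, min(5, t_end), by = 0.02),
                        seq(0, t_end, by = 0.1),
                        schedule$frame_start, schedule$frame_end)))
  ct <- if (params$K1 == 0) numeric(length(grid))
        else tissue_response(params, grid, eval_cp(input_fn, grid))
  total <- (1 - params$vB) * ct
  if (params$vB > 0) total <- total + params$vB * wholeblood_fn(grid)

  # frame average by trapezoid over the dense grid within each frame
  act <- vapply(seq_len(nrow(schedule)), function(i) {
    lo <- schedule$frame_start[i]; hi <- schedule$frame_end[i]
    sel <- grid >= lo - 1e-12 & grid <= hi + 1e-12
    tt <- grid[sel]; vv <- total[sel]
    sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2) / (hi - lo)
  }, numeric(1))

  if (noise_scale > 0) {
    if (!is.null(seed)) set.seed(seed)
    sdv <- noise_scale * sqrt(pmax(act, 0) / schedule$frame_dur)
    act <- act + stats::rnorm(length(act), 0, sdv)
  }
  out <- data.frame(region = region, frame_start = schedule$frame_start,
                    frame_end = schedule$frame_end, activity = act,
                    stringsAsFactors = FALSE)
  class(out) <- c("tac", "data.frame")
  out
}

#' Kinetic parameters that realise a target V_T
#'
#' Convenience for pipeline simulation: holds K1, k3, k4 fixed at plausible
#' values for a reversible tracer and solves for k2 so that the analytic
#' V_T equals \code{vt}.
#'
#' @param vt Target volume of distribution (> 0).
#' @param K1,k3,k4,vB Remaining rate constants.
#' @return A [kinetic_params()] with \code{analytic_vt()} equal to \code{vt}.
#' @export
kinetic_params_for_vt <- function(vt, K1 = 0.3, k3 = 0.05, k4 = 0.05, vB = 0) {
  if (vt <= 0) stop("target vt must be positive", call. = FALSE)
  k2 <- K1 * (1 + ifelse(k3 == 0, 0, k3 / k4)) / vt
  kinetic_params(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB)
}
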