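#' Metabolite-corrected arterial input function
#'
#' A tabulated concentration curve with a declared interpolation contract:
#' piecewise-linear between grid points, zero before the first point, and a
#' mono-exponential tail fitted to the last three points beyond the grid.
#' Integrals under this contract are computed analytically (trapezoid on
#' the grid, closed-form exponential tail).
#'
#' @param time Strictly increasing times (min).
#' @param conc Non-negative concentrations (kBq/mL).
#' @return Object of class \code{input_function}.
#' @export
input_function <- function(time, conc) {
  if (length(time) != length(conc) || length(time) < 2)
    stop("need at least two (time, conc) points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  n <- length(time)
  # mono-exponential tail from the last three points (log-linear LS);
  # degenerate (zero/non-decaying) tails fall back to a constant hold
  last3 <- (n - 2):n
  tl <- time[last3]; cl <- conc[last3]
  if (all(cl > 0)) {
    fit <- stats::lm.fit(cbind(1, tl), log(cl))
    lam <- -fit$coefficients[2]
    if (!is.finite(lam) || lam < 1e-10) {
      lam <- 0; A <- conc[n]
    } else A <- exp(fit$coefficients[1])
  } else {
    lam <- 0; A <- conc[n]
  }
  cum <- c(0, cumsum(diff(time) * (conc[-n] + conc[-1]) / 2))
  structure(list(time = time, conc = conc, cum = cum,
                 tail_A = unname(A), tail_lambda = unname(lam)),
            class = "input_function")
}

#' Evaluate an input function
#' @param f An [input_function()].
#' @param t Times (min), vectorised.
#' @return Concentration (kBq/mL) under the interpolation contract.
#' @export
eval_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  out <- numeric(length(t))
  tmax <- f$time[length(f$time)]
  inside <- t >= f$time[1] & t <= tmax
  if (any(inside))
    out[inside] <- stats::approx(f$time, f$conc, xout = t[inside])$y
  beyond <- t > tmax
  if (any(beyond))
    out[beyond] <- if (f$tail_lambda > 0)
      f$tail_A * exp(-f$tail_lambda * t[beyond]) else f$tail_A
  out
}

#' Integrate an input function from zero
#'
#' \eqn{\int_0^t C_p(s) ds} under the interpolation contract: exact
#' trapezoid inside the grid (zero before the first point), closed-form
#' exponential (or constant) tail beyond it. Non-decreasing in t.
#'
#' @param f An [input_function()].
#' @param t Upper limits (min), vectorised, >= 0. A warning is issued for
#'   t beyond twice the last sample time, where the tail extrapolation is
#'   unvalidated.
#' @return kBq min/mL.
#' @export
integrate_input <- function(f, t) {
  stopifnot(inherits(f, "input_function"))
  if (any(t < 0)) stop("integration limit must be non-negative", call. = FALSE)
  n <- length(f$time)
  tmax <- f$time[n]
  if (any(t > 2 * tmax))
    warning("integrating beyond 2x the last sample time (", tmax,
            " min); tail extrapolation unvalidated there", call. = FALSE)
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= f$time[1]) { out[i] <- 0; next }
    if (ti <= tmax) {
      k <- findInterval(ti, f$time)
      ck <- f$conc[k] + (f$conc[min(k + 1, n)] - f$conc[k]) *
        (ti - f$time[k]) / max(f$time[min(k + 1, n)] - f$time[k], 1e-300)
      out[i] <- f$cum[k] + (f$conc[k] + ck) / 2 * (ti - f$time[k])
    } else {
      tail_part <- if (f$tail_lambda > 0)
        f$tail_A / f$tail_lambda *
          (exp(-f$tail_lambda * tmax) - exp(-f$tail_lambda * ti))
      else f$tail_A * (ti - tmax)
      out[i] <- f$cum[n] + tail_part
    }
  }
  out
}

#' Fit the parent-fraction curve to HPLC measurements
#'
#' Least-squares fit of the gamma-survival ("inverted gamma") form
#' \eqn{p(t) = p_\infty + (1 - p_\infty) Q(\alpha, t/\theta)} to measured
#' parent fractions. If per-sample extraction efficiencies are supplied,
#' measurements are divided by them before fitting. When the nonlinear fit
#' fails to converge the fit falls back to a monotone non-increasing
#' interpolant (isotonic projection, p(0) = 1, constant tail), flagged in
#' the returned object and by a warning.
#'
#' @param samples A \code{blood_samples} table (or any data.frame with
#'   \code{time_min} and \code{parent_fraction}).
#' @param extraction_efficiency Optional vector of efficiencies in (0, 1],
#'   one per parent-fraction measurement.
#' @return Object of class \code{parent_fraction_fit}: \code{p_inf},
#'   \code{alpha}, \code{theta}, \code{fit_residual_rms}, \code{method}
#'   ("gamma_survival" or "monotone_interp").
#' @export
fit_parent_fraction <- function(samples, extraction_efficiency = NULL) {
  ok <- !is.na(samples$parent_fraction)
  tt <- samples$time_min[ok]
  pp <- samples$parent_fraction[ok]
  if (length(tt) < 4)
    stop("insufficient data: need at least 4 parent-fraction measurements, got ",
         length(tt), call. = FALSE)
  if (!is.null(extraction_efficiency)) {
    if (length(extraction_efficiency) != length(pp))
      stop("one extraction efficiency per parent-fraction measurement required",
           call. = FALSE)
    if (any(extraction_efficiency <= 0 | extraction_efficiency > 1))
      stop("extraction efficiencies must lie in (0, 1]", call. = FALSE)
    pp <- pp / extraction_efficiency
  }
  pp <- pmin(pmax(pp, 0), 1)
  ord <- order(tt); tt <- tt[ord]; pp <- pp[ord]

  if (diff(range(pp)) < 1e-9) {
    # constant parent fraction (e.g. no metabolism): the survival form is
    # exact with an arbitrarily fast transient; nonlinear LS is singular here
    return(structure(list(p_inf = pp[1], alpha = 1, theta = 1e-9,
                          fit_residual_rms = 0, method = "gamma_survival"),
                     class = "parent_fraction_fit"))
  }
  dat <- data.frame(t = tt, p = pp)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      p ~ p_inf + (1 - p_inf) * pgamma(t / theta, shape = alpha,
                                       lower.tail = FALSE),
      data = dat,
      start = list(p_inf = max(min(pp) * 0.9, 0.01), alpha = 1.5,
                   theta = max(stats::median(tt) / 2, 1)),
      lower = c(0, 1e-3, 1e-2), upper = c(1, 60, 600),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    rms <- sqrt(mean(stats::resid(fit)^2))
    return(structure(list(p_inf = unname(cf["p_inf"]),
                          alpha = unname(cf["alpha"]),
                          theta = unname(cf["theta"]),
                          fit_residual_rms = rms,
                          method = "gamma_survival"),
                     class = "parent_fraction_fit"))
  }
  warning("gamma-survival fit did not converge; using monotone interpolant",
          call. = FALSE)
  iso <- stats::isoreg(tt, -pp)  # non-increasing projection
  py <- pmin(pmax(-iso$yf, 0), 1)
  knots_t <- c(0, tt); knots_p <- c(1, py)
  structure(list(p_inf = py[length(py)], alpha = NA_real_, theta = NA_real_,
                 fit_residual_rms = sqrt(mean((py - pp)^2)),
                 method = "monotone_interp",
                 knots = list(t = knots_t, p = knots_p)),
            class = "parent_fraction_fit")
}

#' Predict parent fraction from a fit
#' @param object A \code{parent_fraction_fit}.
#' @param t Times (min).
#' @param ... Unused.
#' @return Parent fractions in [0, 1].
#' @export
predict.parent_fraction_fit <- function(object, t, ...) {
  if (object$method == "gamma_survival") {
    parent_fraction_curve(t, object$p_inf, object$alpha, object$theta)
  } else {
    k <- object$knots
    out <- stats::approx(k$t, k$p, xout = pmin(t, max(k$t)), rule = 2)$y
    pmin(pmax(out, 0), 1)
  }
}

#' Build the metabolite-corrected arterial input function
#'
#' Multiplies the total plasma activity curve by the fitted parent-fraction
#' curve point by point on a unified time grid. The early continuous
#' whole-blood segment (first ~7 min) is converted to plasma with a constant
#' plasma-to-whole-blood ratio (median over samples carrying both
#' measurements, unless given) and merged with the discrete draws; where a
#' continuous and a discrete sample coincide in time the discrete one wins.
#'
#' @param samples A \code{blood_samples} table.
#' @param pf A \code{parent_fraction_fit}.
#' @param plasma_ratio Optional fixed plasma-to-whole-blood ratio; default
#'   is the median observed ratio.
#' @return An [input_function()] starting at (0, 0).
#' @export
build_input_function <- function(samples, pf, plasma_ratio = NULL) {
  stopifnot(inherits(pf, "parent_fraction_fit"))
  if (any(samples$plasma_kBq_mL < 0, na.rm = TRUE) ||
      any(samples$wholeblood_kBq_mL < 0, na.rm = TRUE))
    stop("negative blood activities are invalid", call. = FALSE)
  has_pl <- !is.na(samples$plasma_kBq_mL)
  if (is.null(plasma_ratio)) {
    both <- has_pl & !is.na(samples$wholeblood_kBq_mL) &
      samples$wholeblood_kBq_mL > 0
    plasma_ratio <- if (any(both))
      stats::median(samples$plasma_kBq_mL[both] /
                    samples$wholeblood_kBq_mL[both]) else 1
  }
  pl <- ifelse(has_pl, samples$plasma_kBq_mL,
               samples$wholeblood_kBq_mL * plasma_ratio)
  tt <- samples$time_min
  if (anyNA(pl)) stop("plasma activity neither measured nor derivable",
                      call. = FALSE)
  # discrete samples win at duplicated times
  pref <- if (!is.null(samples$source))
    ifelse(samples$source == "discrete", 1L, 0L) else rep(1L, length(tt))
  ord <- order(tt, -pref)
  keep <- !duplicated(tt[ord])
  tt <- tt[ord][keep]; pl <- pl[ord][keep]
  corrected <- pl * predict(pf, tt)
  if (tt[1] > 0) { tt <- c(0, tt); corrected <- c(0, corrected) }
  input_function(tt, corrected)
}
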