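#' MA1 estimate of the regional volume of distribution
#'
#' Multilinear analysis-1 for reversible tracers: over frames with midpoint
#' later than \code{t_star}, the tissue curve is regressed on its own
#' running integral and that of the input,
#' \deqn{C_T(t) = -\frac{V_T}{b}\int_0^t C_p(s)ds + \frac{1}{b}\int_0^t
#'       C_T(s)ds,}
#' by weighted linear least squares, and \eqn{V_T = -\beta_1/\beta_2}. The
#' tissue integral is a trapezoid over frame midpoints with the activity
#' taken as zero at t = 0.
#'
#' @param tac A \code{tac} data.frame (region, frame_start, frame_end,
#'   activity).
#' @param input_fn An [input_function()] covering the scan duration.
#' @param t_star Start time of the linear phase (min); default 30.
#' @param frame_weights "duration" (weights proportional to frame length,
#'   default) or "uniform".
#' @return Object of class \code{vt_estimate}: \code{region}, \code{vt},
#'   \code{b} (min), \code{n_frames_used}, \code{condition_number},
#'   \code{residual_rms}, \code{valid} (vt > 0), \code{method}.
#' @export
ma1_vt <- function(tac, input_fn, t_star = 30,
                   frame_weights = c("duration", "uniform")) {
  frame_weights <- match.arg(frame_weights)
  prep <- graphical_prep(tac, input_fn, t_star)
  w <- if (frame_weights == "duration") prep$dur_used else rep(1, prep$n_used)
  w <- w / sum(w)
  X <- cbind(prep$Scp, prep$Sct)
  y <- prep$ct
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, y * sw)
  beta <- fit$coefficients
  if (!all(is.finite(beta)) || abs(beta[2]) < 1e-12)
    stop("degenerate MA1 fit: 1/b coefficient is numerically zero", call. = FALSE)
  vt <- -beta[1] / beta[2]
  res <- y - drop(X %*% beta)
  new_vt_estimate(region = prep$region, vt = vt, b = 1 / beta[2],
                  n_frames_used = prep$n_used,
                  condition_number = kappa(X * sw, exact = TRUE),
                  residual_rms = sqrt(mean(res^2)), method = "MA1")
}

#' Logan graphical estimate of V_T (internal cross-check)
#'
#' Standard Logan plot: for frames past \code{t_star}, the slope of
#' \eqn{\int_0^t C_T / C_T(t)} against \eqn{\int_0^t C_p / C_T(t)} estimates
#' V_T. Serves as a method-concordance oracle for [ma1_vt()], not a primary
#' output.
#'
#' @inheritParams ma1_vt
#' @return A \code{vt_estimate} (with \code{b} the Logan intercept, min).
#' @export
logan_vt <- function(tac, input_fn, t_star = 30) {
  prep <- graphical_prep(tac, input_fn, t_star)
  if (any(abs(prep$ct) < 1e-12))
    stop("degenerate Logan fit: tissue activity is zero past t*", call. = FALSE)
  x <- prep$Scp / prep$ct
  yv <- prep$Sct / prep$ct
  X <- cbind(1, x)
  fit <- stats::lm.fit(X, yv)
  beta <- fit$coefficients
  if (!all(is.finite(beta)))
    stop("degenerate Logan fit", call. = FALSE)
  res <- yv - drop(X %*% beta)
  new_vt_estimate(region = prep$region, vt = beta[2], b = beta[1],
                  n_frames_used = prep$n_used,
                  condition_number = kappa(X, exact = TRUE),
                  residual_rms = sqrt(mean(res^2)), method = "Logan")
}

# Shared preparation for the graphical estimators: frame midpoints, running
# integrals of tissue (trapezoid, zero origin) and input, t* selection.
graphical_prep <- function(tac, input_fn, t_star) {
  if (is.unsorted(tac$frame_start, strictly = TRUE) ||
      any(tac$frame_end <= tac$frame_start))
    stop("frames must be ordered and non-degenerate", call. = FALSE)
  mids <- (tac$frame_start + tac$frame_end) / 2
  ct <- tac$activity
  if (any(!is.finite(ct))) stop("non-finite activity in TAC", call. = FALSE)
  tt <- c(0, mids); vv <- c(0, ct)
  Sct_all <- cumsum(c(0, diff(tt) * (vv[-length(vv)] + vv[-1]) / 2))[-1]
  sel <- mids > t_star
  if (sum(sel) < 3)
    stop("insufficient frames: need >= 3 frame midpoints beyond t* = ",
         t_star, " min", call. = FALSE)
  list(region = as.character(tac$region[1]),
       ct = ct[sel], Sct = Sct_all[sel],
       Scp = integrate_input(input_fn, mids[sel]),
       dur_used = (tac$frame_end - tac$frame_start)[sel],
       n_used = sum(sel))
}

new_vt_estimate <- function(region, vt, b, n_frames_used, condition_number,
                            residual_rms, method) {
  structure(list(region = region, vt = unname(vt), b = unname(b),
                 n_frames_used = n_frames_used,
                 condition_number = unname(condition_number),
                 residual_rms = unname(residual_rms),
                 valid = is.finite(vt) && vt > 0, method = method),
            class = "vt_estimate")
}

#' @export
print.vt_estimate <- function(x, ...) {
  cat(sprintf("%s V_T estimate [%s]: %.4f (b = %.2f min, %d frames, rms %.3g%s)\n",
              x$region, x$method, x$vt, x$b, x$n_frames_used, x$residual_rms,
              if (x$valid) "" else ", INVALID"))
  invisible(x)
}

#' Relative lobar/cerebellar volumes for the whole-brain composite
#'
#' Approximate relative sizes of the four cerebral lobes and the cerebellum
#' in MNI space (AAL parcellation), used as default weights for the
#' whole-brain composite score. Override with study-specific values where
#' available.
#' @return Named numeric vector summing to 1.
#' @export
aal_lobe_weights <- function() {
  c(frontal = 0.32, temporal = 0.23, parietal = 0.16, occipital = 0.12,
    cerebellum = 0.17)
}

#' Size-weighted whole-brain composite V_T
#'
#' \eqn{\sum_i w_i V_{T,i} / \sum_i w_i} over the valid regional estimates.
#' Estimates flagged invalid (vt <= 0) are excluded; the weight set must
#' match the valid regions exactly.
#'
#' @param estimates A list of \code{vt_estimate} objects or a data.frame
#'   with columns \code{region}, \code{vt} and optionally \code{valid}.
#' @param weights Named weights (> 0), e.g. [aal_lobe_weights()].
#' @return The composite V_T (unitless).
#' @export
composite_whole_brain <- function(estimates, weights = aal_lobe_weights()) {
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  if (is.data.frame(estimates)) {
    valid <- if ("valid" %in% names(estimates)) estimates$valid
             else is.finite(estimates$vt) & estimates$vt > 0
    regions <- as.character(estimates$region[valid])
    vt <- estimates$vt[valid]
  } else {
    valid <- vapply(estimates, `[[`, logical(1), "valid")
    regions <- vapply(estimates[valid], `[[`, character(1), "region")
    vt <- vapply(estimates[valid], `[[`, numeric(1), "vt")
  }
  if (length(vt) == 0)
    stop("empty composite: no valid regional estimates", call. = FALSE)
  if (!setequal(regions, names(weights)))
    stop("weights must be defined for exactly the valid regions; got {",
         paste(regions, collapse = ", "), "} vs weights {",
         paste(names(weights), collapse = ", "), "}", call. = FALSE)
  w <- weights[regions]
  sum(w * vt) / sum(w)
}
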