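# Inverse analysis: phase fits and transport-parameter estimators.

#' Calibrate the probe's elastic coefficient
#'
#' The elastic coefficient beta (MPa m^-3) is the root-pressure change per
#' unit volume change of the probe-root system, measured by imposing step
#' volume changes and recording the pressure response.  The estimate is
#' the least-squares slope of `deltaP` on `deltaV` through the origin.
#'
#' @param volume_steps imposed volume changes, m^3 (non-zero).
#' @param pressure_responses resulting pressure changes, MPa (same
#'   length).
#' @return a list with `beta` (MPa m^-3), per-step `residuals` (MPa), and
#'   `n_steps`.
#' @export
calibrate_beta <- function(volume_steps, pressure_responses) {
  stopifnot(length(volume_steps) == length(pressure_responses),
            length(volume_steps) >= 1)
  if (any(volume_steps == 0)) stop("volume steps must be non-zero", call. = FALSE)
  if (all(pressure_responses == 0))
    stop("no elastic response: all pressure responses are zero", call. = FALSE)
  ratio_sign <- sign(pressure_responses / volume_steps)
  if (length(unique(ratio_sign[ratio_sign != 0])) > 1)
    stop("inconsistent signs across calibration steps", call. = FALSE)
  beta <- sum(pressure_responses * volume_steps) / sum(volume_steps^2)
  list(beta = beta,
       residuals = pressure_responses - beta * volume_steps,
       n_steps = length(volume_steps))
}

#' Fit a single exponential relaxation phase
#'
#' Fits `P(t) = Pinf + A * exp(-k t)` to a window of a pressure trace by
#' nonlinear least squares, seeded from a log-linear regression of
#' `|P - Pinf_hat|` on time.  The rate constant gives the phase half-time
#' `t1/2 = ln 2 / k` from which the transport parameters are computed.
#'
#' @param trace a `pressure_trace` (or data frame with `time_s`,
#'   `pressure_mpa`).
#' @param window numeric length-2 `[t_start, t_end]`; default the full
#'   trace.
#' @param asymptote optional fixed asymptote `Pinf` in MPa; if `NULL`
#'   (default) it is estimated.
#' @return an object of class `"relaxation_fit"`: list with
#'   `rate_constant` (s^-1), `half_time` (s), `asymptote`, `amplitude`
#'   (MPa), `rss` (MPa^2), `n_points`, and the fitted values.
#' @export
fit_exponential_phase <- function(trace, window = NULL, asymptote = NULL) {
  t <- trace$time_s
  p <- trace$pressure_mpa
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; p <- p[keep]
  }
  if (length(t) < 5) stop("need at least 5 samples in the fit window",
                          call. = FALSE)
  t0 <- t[1]
  t <- t - t0
  if (stats::sd(p) == 0) stop("constant trace: no relaxation to fit",
                              call. = FALSE)
  pinf0 <- if (is.null(asymptote)) mean(utils::tail(p, max(3, length(p) %/% 20)))
           else asymptote
  resid0 <- p - pinf0
  amp_sign <- sign(resid0[1])
  if (amp_sign == 0) amp_sign <- sign(mean(utils::head(resid0, 5)))
  y <- amp_sign * resid0
  ok <- y > max(y, 0) * 1e-4
  if (sum(ok) < 5) stop("no exponential decay in window", call. = FALSE)
  # the envelope |P - Pinf| must decay overall, else there is no relaxation
  env <- .moving_average(abs(resid0), max(5L, length(resid0) %/% 20))
  if (stats::cor(t, env) >= 0)
    stop("no exponential decay in window (envelope not decreasing)",
         call. = FALSE)
  seed <- stats::lm(log(y[ok]) ~ t[ok])
  k0 <- -unname(stats::coef(seed)[2])
  if (!is.finite(k0) || k0 <= 0)
    stop("no exponential decay in window (envelope not decreasing)",
         call. = FALSE)
  A0 <- amp_sign * exp(unname(stats::coef(seed)[1]))
  fit <- if (is.null(asymptote)) {
    minpack.lm::nlsLM(p ~ pinf + A * exp(-k * t),
                      start = list(pinf = pinf0, A = A0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(p ~ asymptote + A * exp(-k * t),
                      start = list(A = A0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  k <- unname(cf[["k"]])
  if (k <= 0) stop("fitted rate constant is not positive", call. = FALSE)
  structure(list(
    rate_constant = k,
    half_time = log(2) / k,
    asymptote = if (is.null(asymptote)) unname(cf[["pinf"]]) else asymptote,
    amplitude = unname(cf[["A"]]),
    rss = sum(stats::residuals(fit)^2),
    n_points = length(t),
    time = t + t0,
    fitted = stats::fitted(fit)), class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential phase fit: k = %.4g 1/s (t1/2 = %.3g s), amplitude %.4g MPa,\n  asymptote %.4g MPa, RSS %.3g on %d points\n",
    x$rate_constant, x$half_time, x$amplitude, x$asymptote, x$rss, x$n_points))
  invisible(x)
}

# centered moving average, odd window; ends use shrinking windows
.moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Decompose a biphasic osmotic response
#'
#' Locates the pressure minimum of a biphasic trace (after optional
#' moving-average smoothing), measures the maximum pressure depression
#' `deltaPr = P(0) - P(tmin)` and the time-to-minimum `tmin`, and fits
#' the two phases: the rapid water phase on `[0, tmin]` (free asymptote)
#' and the slow solute phase on `[tmin, end]` with the asymptote fixed at
#' the pre-step pressure `P(0)` (the model recovers fully once the solute
#' has permeated).
#'
#' @param trace a `pressure_trace` from an osmotic-step experiment.
#' @param smooth_window centered moving-average window in samples (odd;
#'   default 5).  Use 1 for no smoothing.
#' @return an object of class `"biphasic_fit"`: list with `tmin` (s),
#'   `deltaPr` (MPa, positive depression), `P0` (MPa), `water_fit` and
#'   `solute_fit` (both [fit_exponential_phase()] results).
#' @export
split_biphasic <- function(trace, smooth_window = 5) {
  stopifnot(nrow(trace) >= 10)
  t <- trace$time_s
  ps <- .moving_average(trace$pressure_mpa, smooth_window)
  imin <- which.min(ps)
  # P0 is the pre-step steady pressure: the raw t = 0 sample (smoothing the
  # first samples would mix in the rapid initial drop and bias deltaPr)
  P0 <- trace$pressure_mpa[1]
  depth <- P0 - ps[imin]
  # noise floor from first differences of the raw trace
  noise <- stats::sd(diff(trace$pressure_mpa)) / sqrt(2)
  if (imin <= 1 || imin >= length(ps) || depth <= 5 * noise ||
      (P0 - ps[length(ps)]) > 0.8 * depth) {
    # monotone (or still falling at the end): impermeant-solute case
    cond <- structure(class = c("rootprobe_no_minimum", "error", "condition"),
                      list(message = paste(
                        "no interior pressure minimum: monotone response",
                        "(impermeant solute, ksr = 0?); plateau depth",
                        sprintf("%.4g MPa", P0 - ps[length(ps)])),
                        call = sys.call()))
    stop(cond)
  }
  tmin <- t[imin]
  water_fit <- fit_exponential_phase(trace, window = c(0, tmin))
  solute_fit <- fit_exponential_phase(trace, window = c(tmin, max(t)),
                                      asymptote = P0)
  structure(list(tmin = tmin, deltaPr = depth, P0 = P0,
                 water_fit = water_fit, solute_fit = solute_fit),
            class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf(
    "Biphasic osmotic response: deltaPr = %.4g MPa at tmin = %.3g s\n  water phase  t1/2 = %.3g s\n  solute phase t1/2 = %.3g s\n",
    x$deltaPr, x$tmin, x$water_fit$half_time, x$solute_fit$half_time))
  invisible(x)
}

#' Hydraulic conductivity from a water-exchange half-time
#'
#' `Lpr = ln 2 / (t1/2w * Ar * beta)`.
#'
#' @param half_time_w half-time of water exchange, s, `> 0`.
#' @param Ar root surface area on the probe, m^2.
#' @param beta probe elastic coefficient, MPa m^-3.
#' @return Lpr in m s^-1 MPa^-1.
#' @export
hydraulic_conductivity <- function(half_time_w, Ar, beta) {
  stopifnot(half_time_w > 0, Ar > 0, beta > 0)
  log(2) / (half_time_w * Ar * beta)
}

#' Solute permeability from a solute-exchange half-time
#'
#' `Psr = ln 2 * Vx / (t1/2s * Ar)`.
#'
#' @param half_time_s half-time of solute exchange, s, `> 0`.
#' @param Ar root surface area on the probe, m^2.
#' @param Vx functional xylem volume, m^3.
#' @return Psr in m s^-1.
#' @export
solute_permeability <- function(half_time_s, Ar, Vx) {
  stopifnot(half_time_s > 0, Ar > 0, Vx > 0)
  log(2) * Vx / (half_time_s * Ar)
}

#' Reflection coefficient from a biphasic response
#'
#' `sigma_sr = (deltaPr / delta_pi) * exp(ksr * tmin)`: the measured
#' pressure depression relative to the osmotic step, corrected for the
#' solute permeation that has already occurred by the time the minimum is
#' reached.
#'
#' @param deltaPr maximum pressure depression, MPa, `>= 0`.
#' @param delta_pi osmotic-pressure step of the medium, MPa, `> 0`.
#' @param ksr solute-permeation rate constant, s^-1.
#' @param tmin time of the pressure minimum, s, `>= 0`.
#' @return the dimensionless reflection coefficient; a warning is issued
#'   if it exceeds 1.
#' @export
reflection_coefficient <- function(deltaPr, delta_pi, ksr, tmin) {
  if (delta_pi <= 0) stop("delta_pi must be positive", call. = FALSE)
  stopifnot(deltaPr >= 0, tmin >= 0, ksr >= 0)
  sigma <- deltaPr / delta_pi * exp(ksr * tmin)
  if (sigma > 1)
    warning(sprintf("reflection coefficient %.3f exceeds 1", sigma),
            call. = FALSE)
  sigma
}

#' Cut-test quality control
#'
#' At the end of a measurement the root is cut close to the seal: a
#' properly mounted root then loses its pressure rapidly (pressure near
#' zero) and its relaxation half-time drops by about an order of
#' magnitude.  Roots failing either check (typically because
#' overtightening blocked the xylem) are discarded.
#'
#' @param pre_cut a [fit_exponential_phase()] result from the pre-cut
#'   hydrostatic relaxations.
#' @param post_cut_trace a `pressure_trace` recorded after the cut, or
#'   `NULL` if missing.
#' @param pressure_threshold pass if the final post-cut pressure falls
#'   below this fraction of the pre-cut steady pressure (default 0.1).
#' @param half_time_ratio pass if the post-cut half-time is at most the
#'   pre-cut half-time divided by this factor (default 10).
#' @return a list with `verdict` (`"pass"`, `"fail"` or
#'   `"indeterminate"`) and `reasons` (character).
#' @export
qc_cut_test <- function(pre_cut, post_cut_trace,
                        pressure_threshold = 0.1, half_time_ratio = 10) {
  stopifnot(inherits(pre_cut, "relaxation_fit"))
  if (is.null(post_cut_trace) || nrow(post_cut_trace) < 5)
    return(list(verdict = "indeterminate",
                reasons = "no post-cut trace recorded"))
  steady <- pre_cut$asymptote
  final_p <- mean(utils::tail(post_cut_trace$pressure_mpa, 5))
  reasons <- character()
  if (final_p > pressure_threshold * steady)
    reasons <- c(reasons, sprintf(
      "root pressure did not drop to near zero (%.3g of steady value); xylem likely blocked at the seal",
      final_p / steady))
  post_fit <- tryCatch(fit_exponential_phase(post_cut_trace),
                       error = function(e) NULL)
  if (is.null(post_fit)) {
    reasons <- c(reasons, "post-cut relaxation could not be fitted")
  } else if (post_fit$half_time > pre_cut$half_time / half_time_ratio) {
    reasons <- c(reasons, sprintf(
      "post-cut half-time (%.3g s) not ~%gx faster than pre-cut (%.3g s)",
      post_fit$half_time, half_time_ratio, pre_cut$half_time))
  }
  list(verdict = if (length(reasons)) "fail" else "pass", reasons = reasons)
}
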