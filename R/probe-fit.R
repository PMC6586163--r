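# probe_fit(): the one-stop estimator tying phase fits to transport
# parameters for a single root.

#' Estimate root transport parameters from pressure-probe traces
#'
#' Fits the composite transport model to the traces recorded for one root:
#' hydrostatic relaxations yield the water-exchange half-time and hence
#' the hydrostatic hydraulic conductivity
#' `Lpr = ln 2 / (t1/2w * Ar * beta)`; a biphasic osmotic response yields
#' the osmotic `Lpr` (from its water phase), the solute permeability
#' `Psr = ln 2 * Vx / (t1/2s * Ar)` (from its solute phase) and the
#' reflection coefficient
#' `sigma = (deltaPr / delta_pi) * exp(ksr * tmin)`.
#'
#' Multiple hydrostatic (push/pull) relaxations per root are fitted
#' individually and their `Lpr` values averaged before any group
#' statistics.  An optional post-cut trace is used for the cut-test
#' quality control.
#'
#' @param hydrostatic a `pressure_trace` or list of traces from
#'   hydrostatic step experiments (may be `NULL` if only osmotic data are
#'   available).
#' @param osmotic a `pressure_trace` from an osmotic step experiment, or
#'   `NULL`.
#' @param probe a [probe_system()] object (beta, Ar).
#' @param geometry a [root_geometry()] object; required when `osmotic`
#'   is given (for the xylem volume).
#' @param delta_pi osmotic-pressure step in MPa; default taken from the
#'   osmotic trace's event annotation.
#' @param post_cut optional post-cut `pressure_trace` for QC.
#' @param smooth_window moving-average window for the minimum search
#'   (samples, default 5).
#' @return an object of class `"probe_fit"` with components
#'   `coefficients` (named vector: `Lpr_hydrostatic`, `Lpr_osmotic`,
#'   `Psr`, `sigma`), `hydro_fits`, `biphasic`, `qc`, and the inputs.
#'   Supports `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate` and `plot`.
#' @examples
#' pr <- probe_system(beta = 1.09e10, Ar = 1.57e-4)
#' ge <- root_geometry()
#' tp <- transport_params(Lpr = 8.11e-8, Psr = 2.24e-9, sigma = 0.38)
#' hy <- simulate_hydrostatic_relaxation(tp, pr)
#' os <- simulate_osmotic_response(tp, pr, ge, delta_pi = 0.148)
#' fit <- probe_fit(hy, os, pr, ge)
#' coef(fit)
#' @export
probe_fit <- function(hydrostatic = NULL, osmotic = NULL, probe, geometry = NULL,
                      delta_pi = NULL, post_cut = NULL, smooth_window = 5) {
  stopifnot(inherits(probe, "probe_system"))
  if (is.null(hydrostatic) && is.null(osmotic))
    stop("need at least one trace", call. = FALSE)
  if (inherits(hydrostatic, "pressure_trace")) hydrostatic <- list(hydrostatic)

  hydro_fits <- lapply(hydrostatic, fit_exponential_phase)
  Lpr_h <- if (length(hydro_fits)) {
    mean(vapply(hydro_fits, function(f)
      hydraulic_conductivity(f$half_time, probe$Ar, probe$beta), numeric(1)))
  } else NA_real_

  biph <- NULL
  notes <- character()
  Lpr_o <- Psr <- sigma <- NA_real_
  if (!is.null(osmotic)) {
    if (is.null(geometry))
      stop("geometry is required to analyze an osmotic trace", call. = FALSE)
    if (is.null(delta_pi)) delta_pi <- attr(osmotic, "event_magnitude")
    if (is.null(delta_pi) || !is.finite(delta_pi) || delta_pi <= 0)
      stop("delta_pi (osmotic step, MPa) missing from trace annotation",
           call. = FALSE)
    biph <- tryCatch(split_biphasic(osmotic, smooth_window = smooth_window),
                     rootprobe_no_minimum = function(e) e)
    if (inherits(biph, "rootprobe_no_minimum")) {
      # solute phase unmeasurable within this trace (impermeant or very
      # slowly permeating solute): leave the solute quantities NA
      notes <- conditionMessage(biph)
      biph <- NULL
    } else {
      Lpr_o <- hydraulic_conductivity(biph$water_fit$half_time, probe$Ar,
                                      probe$beta)
      Vx <- xylem_volume(geometry)
      Psr <- solute_permeability(biph$solute_fit$half_time, probe$Ar, Vx)
      ksr <- biph$solute_fit$rate_constant
      sigma <- reflection_coefficient(biph$deltaPr, delta_pi, ksr, biph$tmin)
    }
  }

  qc <- if (!is.null(post_cut) && length(hydro_fits)) {
    qc_cut_test(hydro_fits[[1]], post_cut)
  } else list(verdict = "indeterminate", reasons = "no post-cut trace")

  structure(list(
    coefficients = c(Lpr_hydrostatic = Lpr_h, Lpr_osmotic = Lpr_o,
                     Psr = Psr, sigma = sigma),
    hydro_fits = hydro_fits, biphasic = biph, qc = qc, notes = notes,
    probe = probe, geometry = geometry, delta_pi = delta_pi,
    traces = list(hydrostatic = hydrostatic, osmotic = osmotic)),
    class = "probe_fit")
}

#' @export
coef.probe_fit <- function(object, ...) object$coefficients

#' @export
print.probe_fit <- function(x, ...) {
  cf <- x$coefficients
  cat("Root pressure-probe fit (composite transport model)\n")
  cat(sprintf("  hydrostatic Lpr: %s m/s/MPa (%d relaxation%s)\n",
              .fmt(cf["Lpr_hydrostatic"]), length(x$hydro_fits),
              if (length(x$hydro_fits) == 1) "" else "s"))
  if (!is.null(x$biphasic)) {
    cat(sprintf("  osmotic Lpr:     %s m/s/MPa\n", .fmt(cf["Lpr_osmotic"])))
    cat(sprintf("  Psr:             %s m/s\n", .fmt(cf["Psr"])))
    cat(sprintf("  sigma:           %.3f\n", cf["sigma"]))
  }
  cat(sprintf("  cut-test QC: %s\n", x$qc$verdict))
  invisible(x)
}

.fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.3g", x)

#' @export
summary.probe_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- list(
    coefficients = cf,
    scaled = c(`Lpr_hydrostatic (1e-8 m/s/MPa)` = unname(cf["Lpr_hydrostatic"]) * 1e8,
               `Lpr_osmotic (1e-8 m/s/MPa)` = unname(cf["Lpr_osmotic"]) * 1e8,
               `Psr (1e-9 m/s)` = unname(cf["Psr"]) * 1e9,
               sigma = unname(cf["sigma"])),
    half_times = c(
      t_half_w = if (length(object$hydro_fits))
        mean(vapply(object$hydro_fits, `[[`, numeric(1), "half_time"))
      else NA_real_,
      t_half_s = if (!is.null(object$biphasic))
        object$biphasic$solute_fit$half_time else NA_real_),
    deltaPr = if (!is.null(object$biphasic)) object$biphasic$deltaPr else NA_real_,
    tmin = if (!is.null(object$biphasic)) object$biphasic$tmin else NA_real_,
    qc = object$qc)
  class(out) <- "summary.probe_fit"
  out
}

#' @export
print.summary.probe_fit <- function(x, ...) {
  cat("Transport parameters (conventional units):\n")
  print(round(x$scaled, 3))
  cat(sprintf("half-times: t1/2w = %.3g s, t1/2s = %.3g s\n",
              x$half_times["t_half_w"], x$half_times["t_half_s"]))
  if (is.finite(x$tmin))
    cat(sprintf("biphasic minimum: deltaPr = %.4g MPa at tmin = %.3g s\n",
                x$deltaPr, x$tmin))
  cat(sprintf("QC: %s\n", x$qc$verdict))
  invisible(x)
}

# model curves implied by the fitted phase parameters
.predict_hydro <- function(fit, t) fit$asymptote + fit$amplitude *
  exp(-fit$rate_constant * t)

#' @export
predict.probe_fit <- function(object, newdata = NULL, ...) {
  out <- list()
  if (length(object$hydro_fits)) {
    f <- object$hydro_fits[[1]]
    t <- if (is.null(newdata)) object$traces$hydrostatic[[1]]$time_s
         else newdata$time_s
    out$hydrostatic <- data.frame(time_s = t,
                                  pressure_mpa = .predict_hydro(f, t))
  }
  if (!is.null(object$biphasic)) {
    b <- object$biphasic
    kwr <- b$water_fit$rate_constant
    ksr <- b$solute_fit$rate_constant
    t <- if (is.null(newdata)) object$traces$osmotic$time_s else newdata$time_s
    # amplitude chosen so the model curve reaches the measured minimum
    S <- b$deltaPr / osmotic_deviation(b$tmin, kwr, ksr)
    out$osmotic <- data.frame(time_s = t,
                              pressure_mpa = b$P0 - S *
                                osmotic_deviation(t, kwr, ksr))
  }
  out
}

#' @export
residuals.probe_fit <- function(object, ...) {
  pred <- predict(object)
  out <- list()
  if (!is.null(pred$hydrostatic))
    out$hydrostatic <- object$traces$hydrostatic[[1]]$pressure_mpa -
      pred$hydrostatic$pressure_mpa
  if (!is.null(pred$osmotic))
    out$osmotic <- object$traces$osmotic$pressure_mpa -
      pred$osmotic$pressure_mpa
  out
}

#' @export
simulate.probe_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.002, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  params <- transport_params(Lpr = unname(cf["Lpr_hydrostatic"]),
                             Psr = if (is.finite(cf["Psr"])) unname(cf["Psr"]) else 0,
                             sigma = if (is.finite(cf["sigma"]))
                               min(1, unname(cf["sigma"])) else 1)
  replicate(nsim, simulate_hydrostatic_relaxation(
    params, object$probe, noise_sd = noise_sd), simplify = FALSE)
}

#' @export
plot.probe_fit <- function(x, ...) {
  pred <- predict(x)
  n_panel <- length(pred)
  if (n_panel == 0) stop("nothing to plot", call. = FALSE)
  old <- graphics::par(mfrow = c(1, n_panel)); on.exit(graphics::par(old))
  if (!is.null(pred$hydrostatic)) {
    tr <- x$traces$hydrostatic[[1]]
    plot(tr$time_s, tr$pressure_mpa, pch = ".", xlab = "time (s)",
         ylab = "root pressure (MPa)", main = "hydrostatic relaxation", ...)
    graphics::lines(pred$hydrostatic, col = 2, lwd = 2)
  }
  if (!is.null(pred$osmotic)) {
    tr <- x$traces$osmotic
    plot(tr$time_s, tr$pressure_mpa, pch = ".", xlab = "time (s)",
         ylab = "root pressure (MPa)", main = "osmotic response", ...)
    graphics::lines(pred$osmotic, col = 2, lwd = 2)
    graphics::abline(v = x$biphasic$tmin, lty = 2)
  }
  invisible(x)
}
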