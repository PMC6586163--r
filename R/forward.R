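# Forward model: pressure-probe kinetics under the composite transport model.
#
# Hydrostatic relaxation: a pressure step deltaP0 imposed by the probe rod
# relaxes back to the steady root pressure as water crosses the root,
#   P(t) = P_ss + deltaP0 * exp(-kwr t),      kwr = Lpr * Ar * beta.
# Osmotic response: a step delta_pi in medium osmotic pressure drives a
# rapid exosmotic water phase followed by a slower recovery as the solute
# permeates (rate ksr = Ar * Psr / Vx), giving the biphasic curve
#   P(t) = P0 - sigma * delta_pi * kwr/(kwr - ksr) * (e^{-ksr t} - e^{-kwr t}).

#' Rate constant of water exchange
#'
#' `kwr = Lpr * Ar * beta`; the half-time of water exchange is
#' `t1/2w = ln 2 / kwr`.
#'
#' @param params a [transport_params()] object.
#' @param probe a [probe_system()] object.
#' @return rate constant in s^-1.
#' @export
hydrostatic_rate_constant <- function(params, probe) {
  stopifnot(inherits(params, "transport_params"), inherits(probe, "probe_system"))
  params$Lpr * probe$Ar * probe$beta
}

#' Rate constant of solute permeation
#'
#' `ksr = Ar * Psr / Vx` with `Vx` the functional xylem volume; the
#' half-time of solute exchange is `t1/2s = ln 2 / ksr`.
#'
#' @inheritParams hydrostatic_rate_constant
#' @param geom a [root_geometry()] object.
#' @return rate constant in s^-1 (0 for an impermeant solute).
#' @export
solute_rate_constant <- function(params, probe, geom) {
  stopifnot(inherits(params, "transport_params"), inherits(probe, "probe_system"))
  Vx <- xylem_volume(geom)
  if (Vx <= 0) stop("functional xylem volume must be positive", call. = FALSE)
  probe$Ar * params$Psr / Vx
}

#' Time of the pressure minimum of a biphasic osmotic response
#'
#' Stationarity of the double exponential gives
#' `tmin = ln(kwr / ksr) / (kwr - ksr)`.
#'
#' @param kwr water-exchange rate constant, s^-1, `> ksr`.
#' @param ksr solute-permeation rate constant, s^-1, `> 0`.
#' @return time of the minimum in s.
#' @export
analytic_tmin <- function(kwr, ksr) {
  stopifnot(kwr > 0)
  if (ksr <= 0)
    stop("impermeant solute (ksr = 0): the response has no finite minimum",
         call. = FALSE)
  if (ksr >= kwr) stop("requires kwr > ksr", call. = FALSE)
  log(kwr / ksr) / (kwr - ksr)
}

# depth of the minimum below P0, analytic (positive magnitude)
.analytic_deltaPr <- function(kwr, ksr, sigma, delta_pi) {
  tm <- analytic_tmin(kwr, ksr)
  sigma * delta_pi * kwr / (kwr - ksr) * (exp(-ksr * tm) - exp(-kwr * tm))
}

.new_trace <- function(time, pressure, event_kind, event_magnitude) {
  stopifnot(length(time) >= 2, all(diff(time) > 0), all(is.finite(pressure)))
  structure(data.frame(time_s = time, pressure_mpa = pressure),
            event_kind = event_kind, event_magnitude = event_magnitude,
            class = c("pressure_trace", "data.frame"))
}

#' Simulate a hydrostatic pressure relaxation
#'
#' Single-exponential return to the steady-state root pressure after a
#' pressure offset imposed with the probe's micrometer screw:
#' `P(t) = P_ss + deltaP0 * exp(-kwr t)`.
#'
#' @inheritParams hydrostatic_rate_constant
#' @param P_ss steady-state root pressure, MPa.
#' @param deltaP0 initial pressure offset, MPa (either sign).
#' @param duration trace length, s (`>= 10 * dt`).
#' @param dt sampling interval, s, `> 0`.
#' @param noise_sd Gaussian sensor noise standard deviation, MPa
#'   (default 0 = noise-free).
#' @return a `pressure_trace` data frame with columns `time_s`,
#'   `pressure_mpa` and attributes `event_kind`, `event_magnitude`.
#' @export
simulate_hydrostatic_relaxation <- function(params, probe, P_ss = 0.2,
                                            deltaP0 = 0.05, duration = 60,
                                            dt = 0.05, noise_sd = 0) {
  stopifnot(dt > 0, duration >= 10 * dt, noise_sd >= 0)
  kwr <- hydrostatic_rate_constant(params, probe)
  t <- seq(0, duration, by = dt)
  p <- P_ss + deltaP0 * exp(-kwr * t)
  if (noise_sd > 0) p <- p + stats::rnorm(length(p), 0, noise_sd)
  .new_trace(t, p, "hydrostatic_step", deltaP0)
}

#' Simulate a biphasic osmotic pressure response
#'
#' Response of root pressure to a step increase `delta_pi` in the osmotic
#' pressure of the medium: a rapid exosmotic water phase (rate `kwr`)
#' lowers root pressure to a minimum, after which solute permeation (rate
#' `ksr`) dissipates the osmotic gradient and pressure recovers to `P0`.
#' The closed form is
#' `P(t) = P0 - sigma * delta_pi * kwr/(kwr - ksr) * (e^{-ksr t} - e^{-kwr t})`,
#' with the degenerate `ksr = kwr` case handled by its analytic limit
#' `-sigma * delta_pi * kwr * t * e^{-kwr t}` and `ksr = 0` giving a
#' monotone drop to `P0 - sigma * delta_pi` (impermeant solute).
#'
#' @inheritParams solute_rate_constant
#' @param P0 pre-step steady root pressure, MPa.
#' @param delta_pi osmotic-pressure step of the medium, MPa, `> 0`.
#' @param duration trace length, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian sensor noise sd, MPa (default 0).
#' @return a `pressure_trace` (see
#'   [simulate_hydrostatic_relaxation()]).
#' @export
simulate_osmotic_response <- function(params, probe, geom, P0 = 0.2,
                                      delta_pi, duration = 3000, dt = 0.1,
                                      noise_sd = 0) {
  stopifnot(delta_pi > 0, dt > 0, duration >= 10 * dt, noise_sd >= 0)
  kwr <- hydrostatic_rate_constant(params, probe)
  if (kwr <= 0) stop("kwr must be positive", call. = FALSE)
  ksr <- solute_rate_constant(params, probe, geom)
  t <- seq(0, duration, by = dt)
  dev <- osmotic_deviation(t, kwr, ksr)
  p <- P0 - params$sigma * delta_pi * dev
  if (noise_sd > 0) p <- p + stats::rnorm(length(p), 0, noise_sd)
  .new_trace(t, p, "osmotic_step", delta_pi)
}

#' Unit-amplitude deviation kernel of the osmotic response
#'
#' The dimensionless factor multiplying `sigma * delta_pi` in the osmotic
#' response, `kwr/(kwr-ksr) * (e^{-ksr t} - e^{-kwr t})`, with its
#' `ksr -> kwr` limit `kwr * t * e^{-kwr t}` and `ksr = 0` limit
#' `1 - e^{-kwr t}`.  Exposed for testing and for predict methods.
#'
#' @param t time vector, s.
#' @param kwr,ksr rate constants, s^-1.
#' @return numeric vector of the same length as `t`.
#' @export
osmotic_deviation <- function(t, kwr, ksr) {
  stopifnot(kwr > 0, ksr >= 0)
  if (ksr == kwr) return(kwr * t * exp(-kwr * t))
  kwr / (kwr - ksr) * (exp(-ksr * t) - exp(-kwr * t))
}
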