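# Osmoticum calibration and osmotic-pressure bookkeeping.

#' Universal gas constant, J mol^-1 K^-1
#' @keywords internal
R_GAS <- 8.314

# Michel (1983) PEG-8000 calibration coefficients: water potential in bar as
# a function of concentration C and temperature T (degrees C),
#   psi_bar = 1.29*T*C^2 - 140*C^2 - 4.0*C .
# C is interpreted as the w/w mass fraction of PEG 8000 in the *total*
# solution; with that convention and T = 23 C the calibration maps
# 17.5/25.4/31.6 % w/w to -0.4/-0.8/-1.2 MPa (one decimal).
.michel_coef <- c(t_quad = 1.29, quad = -140, lin = -4.0)

#' Water potential of a PEG-8000 solution
#'
#' Evaluates the empirical PEG-8000 calibration polynomial relating the
#' mass fraction of PEG 8000 in solution and temperature to the solution's
#' water potential.  PEG 8000 is a high-molecular-weight osmoticum that
#' lowers the water potential of a hydroponic medium without being taken
#' up by roots, which makes it the standard agent for imposing defined
#' osmotic (water-deficit) stress.
#'
#' @param mass_fraction PEG-8000 mass fraction of the total solution
#'   (w/w, dimensionless), in `[0, 0.45]`.  Vectorised.
#' @param temperature solution temperature in degrees Celsius, in
#'   `[5, 40]`.  Defaults to 23, a typical day growth temperature.
#' @return Water potential in MPa (always `<= 0`; 0 for pure solvent).
#' @examples
#' peg8000_water_potential(c(0.175, 0.254, 0.316))  # about -0.4, -0.8, -1.2
#' @seealso [peg8000_mass_fraction()] for the inverse lookup,
#'   [vant_hoff_osmotic_pressure()] for dilute-solute osmotic pressure.
#' @export
peg8000_water_potential <- function(mass_fraction, temperature = 23) {
  if (any(!is.finite(mass_fraction)) || any(mass_fraction < 0) ||
      any(mass_fraction > 0.45)) {
    stop("mass_fraction must lie in the calibration range [0, 0.45]",
         call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(temperature < 5) ||
      any(temperature > 40)) {
    stop("temperature must lie in the calibration range [5, 40] degrees C",
         call. = FALSE)
  }
  co <- .michel_coef
  psi_bar <- (co[["t_quad"]] * temperature + co[["quad"]]) * mass_fraction^2 +
    co[["lin"]] * mass_fraction
  psi_bar / 10  # bar -> MPa
}

#' PEG-8000 mass fraction for a target water potential
#'
#' Inverse of [peg8000_water_potential()]: finds by bisection the w/w mass
#' fraction of PEG 8000 that brings the medium to a target water potential
#' at a given temperature.
#'
#' @param target_mpa target water potential in MPa, must be `<= 0` and
#'   within the reach of the calibration (about -3 MPa at 23 degrees C).
#' @param temperature degrees Celsius (default 23).
#' @return mass fraction (w/w of total solution).
#' @export
peg8000_mass_fraction <- function(target_mpa, temperature = 23) {
  if (length(target_mpa) != 1 || !is.finite(target_mpa) || target_mpa > 0)
    stop("target_mpa must be a single non-positive value", call. = FALSE)
  lo <- peg8000_water_potential(0.45, temperature)
  if (target_mpa < lo)
    stop(sprintf("target %.2f MPa below calibration reach (%.2f MPa at %.0f C)",
                 target_mpa, lo, temperature), call. = FALSE)
  if (target_mpa == 0) return(0)
  stats::uniroot(function(f) peg8000_water_potential(f, temperature) - target_mpa,
                 interval = c(0, 0.45), tol = 1e-10)$root
}

#' Van't Hoff osmotic pressure of a dilute solution
#'
#' Computes the osmotic pressure `pi = R * T * Cs` of a dilute solution,
#' with `Cs` the osmolality of the solute.  For dilute aqueous media,
#' 1 mOsmol kg^-1 is taken as 1 mol m^-3.  This is the osmotic-pressure
#' step `delta pi0_s` applied in osmotic pressure-probe experiments.
#'
#' @param osmolality solute osmolality in mOsmol kg^-1 (`>= 0`).
#' @param temperature degrees Celsius (default 23).
#' @return osmotic pressure in MPa (positive).
#' @examples
#' vant_hoff_osmotic_pressure(60)  # 30 mM NaCl step, about 0.148 MPa
#' @export
vant_hoff_osmotic_pressure <- function(osmolality, temperature = 23) {
  if (any(!is.finite(osmolality)) || any(osmolality < 0))
    stop("osmolality must be non-negative", call. = FALSE)
  R_GAS * (temperature + 273.15) * osmolality * 1e-6  # Pa -> MPa
}

#' Ideal osmolality of a dissociating solute
#'
#' Dilute ideal approximation: osmolality equals molar concentration times
#' the number of osmotically active particles per formula unit (2 for
#' NaCl), so 30 mM NaCl contributes 60 mOsmol kg^-1.
#'
#' @param molar_concentration concentration in mM (`>= 0`).
#' @param dissociation_number integer number of particles per formula unit
#'   (`>= 1`).
#' @return osmolality in mOsmol kg^-1.
#' @export
ideal_osmolality <- function(molar_concentration, dissociation_number = 1) {
  if (any(!is.finite(molar_concentration)) || any(molar_concentration < 0))
    stop("molar_concentration must be non-negative", call. = FALSE)
  if (any(dissociation_number < 1) ||
      any(dissociation_number != round(dissociation_number)))
    stop("dissociation_number must be a positive integer", call. = FALSE)
  molar_concentration * dissociation_number
}
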