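# Probe and root geometry containers.

#' Transport parameter triple of a root
#'
#' The composite transport model describes radial water and solute flow
#' across a root in terms of three effective parameters: the hydraulic
#' conductivity `Lpr` (m s^-1 MPa^-1), the solute permeability `Psr`
#' (m s^-1) and the reflection coefficient `sigma` (dimensionless in
#' `[0, 1]`; 1 = ideally semipermeable, 0 = unselective).
#'
#' @param Lpr hydraulic conductivity, m s^-1 MPa^-1, `> 0`.
#' @param Psr solute permeability, m s^-1, `>= 0`.
#' @param sigma reflection coefficient in `[0, 1]`.
#' @return an object of class `"transport_params"`.
#' @export
transport_params <- function(Lpr, Psr = 0, sigma = 1) {
  stopifnot(is.finite(Lpr), Lpr > 0, is.finite(Psr), Psr >= 0,
            is.finite(sigma), sigma >= 0, sigma <= 1)
  structure(list(Lpr = Lpr, Psr = Psr, sigma = sigma),
            class = "transport_params")
}

#' Pressure-probe measuring system
#'
#' @param beta elastic coefficient of the measuring system, MPa m^-3,
#'   `> 0`: the root-pressure change per unit volume change imposed by the
#'   probe's metal rod.
#' @param Ar surface area of the root segment mounted on the probe, m^2,
#'   `> 0`.
#' @return an object of class `"probe_system"`.
#' @export
probe_system <- function(beta, Ar) {
  stopifnot(is.finite(beta), beta > 0, is.finite(Ar), Ar > 0)
  structure(list(beta = beta, Ar = Ar), class = "probe_system")
}

#' Root geometry for xylem-volume bookkeeping
#'
#' The functional (conductive) xylem occupies a small fraction of the root
#' cylinder; its volume enters the solute rate constant
#' `ksr = Ar * Psr / Vx`.  A short apical part of the segment is
#' hydraulically isolated (non-conductive) and excluded from the
#' conductive length.
#'
#' @param conductive_length conductive root length, m, `> 0`.
#' @param root_diameter root diameter, m, `> 0`.
#' @param endodermis_radius endodermis radius, m, `< root_diameter / 2`.
#' @param xylem_fraction fraction of the root cylinder occupied by
#'   functional xylem (default 0.015, i.e. 1.5 %).
#' @param nonconductive_tip_length hydraulically isolated tip length, m
#'   (default 0.015).
#' @return an object of class `"root_geometry"`.
#' @export
root_geometry <- function(conductive_length = 0.10,
                          root_diameter = 5e-4,
                          endodermis_radius = 2e-4,
                          xylem_fraction = 0.015,
                          nonconductive_tip_length = 0.015) {
  stopifnot(conductive_length > 0, root_diameter > 0,
            xylem_fraction > 0, xylem_fraction <= 1,
            endodermis_radius > 0, endodermis_radius < root_diameter / 2,
            nonconductive_tip_length >= 0)
  structure(list(conductive_length = conductive_length,
                 root_diameter = root_diameter,
                 endodermis_radius = endodermis_radius,
                 xylem_fraction = xylem_fraction,
                 nonconductive_tip_length = nonconductive_tip_length),
            class = "root_geometry")
}

#' Functional xylem volume of a root segment
#'
#' `Vx = xylem_fraction * pi * (d/2)^2 * L`, the total cylinder volume of
#' the conductive length scaled by the measured xylem fraction.
#'
#' @param geom a [root_geometry()] object.
#' @return volume in m^3.
#' @export
xylem_volume <- function(geom) {
  stopifnot(inherits(geom, "root_geometry"))
  geom$xylem_fraction * pi * (geom$root_diameter / 2)^2 *
    geom$conductive_length
}

#' Endodermal surface area of a root zone
#'
#' `A = 2 * pi * r * L`, the lateral surface of the endodermal cylinder,
#' used to normalize suberin amounts (micrograms per cm^2 of endodermis).
#'
#' @param endodermis_radius endodermis radius in cm, `> 0`.
#' @param zone_length length of the root zone in cm, `>= 0`.
#' @return area in cm^2.
#' @export
endodermal_surface_area <- function(endodermis_radius, zone_length) {
  if (any(endodermis_radius <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(zone_length < 0)) stop("zone length must be non-negative", call. = FALSE)
  2 * pi * endodermis_radius * zone_length
}
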