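#' Pressure applied to the tissue at a given infusion rate
#'
#' Empirical linear correlation between volumetric infusion rate and the
#' pressure acting on a unit surface of the tissue at the needle tip,
#' `p[kPa] = 0.74 q + 23` with `q` in uL/s.
#'
#' @param q flow rate (>= 0), scalar or vector.
#' @param flow_unit unit of `q`; converted to uL/s internally.
#' @return pressure in kPa.
#' @examples
#' injection_pressure(25, "uL/min")  # 23.31 kPa
#' injection_pressure(0)             # 23 kPa intercept
#' @export
injection_pressure <- function(q, flow_unit = "uL/s") {
  q <- convert_flow(q, flow_unit, "uL/s")
  if (any(q < 0)) stop("flow rate must be non-negative")
  depot_constants$pressure_slope * q + depot_constants$pressure_intercept
}

#' Tissue resistance pressure at a given infusion rate
#'
#' Empirical back-pressure the injection device must overcome,
#' `TRP[kPa] = 10.4 q + 1.14` with `q` in mL/min. At 0.025 and 0.1 mL/min
#' this gives 1.4 and 2.2 kPa.
#'
#' @param q flow rate (>= 0), scalar or vector.
#' @param flow_unit unit of `q`; converted to mL/min internally.
#' @return pressure in kPa.
#' @examples
#' tissue_resistance_pressure(0.025)           # 1.40
#' tissue_resistance_pressure(100, "uL/min")   # 2.18
#' @export
tissue_resistance_pressure <- function(q, flow_unit = "mL/min") {
  q <- convert_flow(q, flow_unit, "mL/min")
  if (any(q < 0)) stop("flow rate must be non-negative")
  depot_constants$trp_slope * q + depot_constants$trp_intercept
}

#' Radial seepage velocity of a point source
#'
#' For a point source emitting volumetric flow `q`, the superficial radial
#' velocity at distance `r` is `v(r) = q / (4 pi r^2)`.
#'
#' @param q flow rate, m^3/s.
#' @param r radial distance, m (> 0).
#' @return velocity in m/s.
#' @export
radial_velocity <- function(q, r) {
  if (any(r <= 0)) stop("r must be > 0")
  q / (4 * pi * r^2)
}

#' Darcy permeability of tissue from a point-source injection
#'
#' Combines Darcy's law with the point-source velocity field: integrating
#' `-k dp/dr = q/(4 pi r^2)` from the depot radius outwards gives
#' `p_t = q / (4 pi k r_t)`, hence `k = q / (4 pi p r_t)` with all
#' quantities in SI. The permeability is reported in m^4/(N s).
#'
#' @param q flow rate (see `flow_unit`).
#' @param r_t depot (bolus) radius at the time of interest, m.
#' @param p pressure applied at the depot surface, kPa. Typically
#'   [injection_pressure()] evaluated at the same flow rate.
#' @param flow_unit unit of `q` (default uL/min).
#' @return permeability k in m^4/(N s).
#' @examples
#' p <- injection_pressure(25, "uL/min")
#' permeability_darcy(25, r_t = 4.924e-3, p = p)  # ~2.9e-13
#' @export
permeability_darcy <- function(q, r_t, p, flow_unit = "uL/min") {
  q_si <- convert_flow(q, flow_unit, "m3/s")
  if (any(q_si <= 0) || any(r_t <= 0) || any(p <= 0)) {
    stop("q, r_t and p must all be > 0")
  }
  q_si / (4 * pi * (p * 1000) * r_t)
}

#' Compact permeability form with the pressure correlation substituted
#'
#' Substituting the empirical applied-pressure correlation
#' `p = 0.74 q + 23` (q in uL/s) into `k = q/(4 pi p r_t)` gives the
#' compact form `k = 1/(2.96 pi r_t) * q/(q + 31.08)` with `q` in uL/s,
#' `r_t` in m and the result scaled by 1e-12 to return SI m^4/(N s)
#' (the unit factor absorbed by expressing q in uL/s and p in kPa).
#'
#' @inheritParams permeability_darcy
#' @return permeability k in m^4/(N s); equal to
#'   `permeability_darcy(q, r_t, injection_pressure(q))`.
#' @export
permeability_compact <- function(q, r_t, flow_unit = "uL/min") {
  q_uls <- convert_flow(q, flow_unit, "uL/s")
  if (any(q_uls <= 0) || any(r_t <= 0)) stop("q and r_t must be > 0")
  1e-12 / (depot_constants$compact_k_factor * r_t) *
    (q_uls / (q_uls + depot_constants$compact_k_shift))
}

#' Spherical wetting-front radius under constant infusion
#'
#' Volume balance for a spherical depot filled at constant rate:
#' `epsilon * (4/3) pi WF^3 = q t`, so
#' `WF(t) = (3 q t / (4 pi epsilon))^(1/3)`.
#'
#' @param q flow rate (see `flow_unit`).
#' @param t time since onset of tissue filling, s (>= 0); vectorised.
#' @param epsilon effective volume fraction in (0, 1].
#' @param flow_unit unit of `q` (default uL/min).
#' @return wetting-front radius in m.
#' @examples
#' wf_spherical(25, 1200)   # end of 500 uL at 25 uL/min: 4.924 mm
#' @export
wf_spherical <- function(q, t, epsilon = 1, flow_unit = "uL/min") {
  if (!(epsilon > 0 && epsilon <= 1)) stop("epsilon must be in (0, 1]")
  if (any(t < 0)) stop("t must be >= 0")
  q_si <- convert_flow(q, flow_unit, "m3/s")
  (3 * q_si * t / (4 * pi * epsilon))^(1 / 3)
}

#' Normalized wetting front
#'
#' The wetting front divided by its value at the end of infusion,
#' `R(t) = WF(t)/WF_m = (q t / Q)^(1/3)`; independent of `epsilon`.
#'
#' @param q flow rate, uL/min.
#' @param t time, s (>= 0); vectorised.
#' @param Q total injected volume, uL (> 0).
#' @return dimensionless normalized front, 1 at the end of infusion.
#' @export
normalized_wf <- function(q, t, Q) {
  if (Q <= 0) stop("Q must be > 0")
  v <- q * t / 60
  if (any(v < 0)) stop("q*t must be >= 0")
  (v / Q)^(1 / 3)
}

#' Fracture toughness of a pressurized micro-crack
#'
#' Energy-release rate for tunnelling fracture of a micro-crack of width
#' `h` in tissue of Young's modulus `E` under pressure `P`:
#' `J = P^2 h / (1.27 E)` (evaluated in SI, returned in J/m^2).
#'
#' @param P pressure, kPa (> 0).
#' @param h crack width, um (> 0).
#' @param E Young's modulus, kPa (> 0).
#' @return fracture toughness J in J/m^2.
#' @examples
#' fracture_toughness(23.3, 800, 1.01)  # ~340 J/m^2
#' fracture_toughness(94,   800, 1.01)  # ~5.5 kJ/m^2
#' @export
fracture_toughness <- function(P, h, E) {
  if (any(P <= 0) || any(h <= 0) || any(E <= 0)) {
    stop("P, h and E must all be > 0")
  }
  (P * 1000)^2 * (h * 1e-6) / (depot_constants$fracture_factor * E * 1000)
}

#' Young's modulus implied by a pressure/toughness pair
#'
#' Inverts `J = P^2 h / (1.27 E)` for `E`, e.g. to anchor the modulus on a
#' known (P, J) operating point.
#'
#' @param P pressure, kPa (> 0).
#' @param J fracture toughness, J/m^2 (> 0).
#' @param h crack width, um (> 0).
#' @return Young's modulus E in kPa.
#' @export
youngs_modulus_from_fracture <- function(P, J, h) {
  if (any(P <= 0) || any(J <= 0) || any(h <= 0)) {
    stop("P, J and h must all be > 0")
  }
  (P * 1000)^2 * (h * 1e-6) / (depot_constants$fracture_factor * J) / 1000
}

#' Classify an injection as fracturing or non-fracturing
#'
#' Compares the fracture toughness generated by the injection with the
#' tissue threshold `J_a`; at or above threshold the pressurized solution
#' is taken to open a micro-crack network (`"fracture"`), below it the
#' solution permeates without fracturing (`"no_fracture"`).
#'
#' @param J fracture toughness of the injection, J/m^2 (>= 0).
#' @param J_a tissue fracture threshold, J/m^2 (>= 0).
#' @return An object of class `"fracture_assessment"`: list with `J`,
#'   `J_a` and `regime`.
#' @examples
#' assess_fracture(340, 4100)   # no_fracture
#' assess_fracture(5500, 4100)  # fracture
#' @export
assess_fracture <- function(J, J_a) {
  if (J < 0 || J_a < 0) stop("J and J_a must be >= 0")
  structure(list(
    J = J, J_a = J_a,
    regime = if (J >= J_a) "fracture" else "no_fracture"
  ), class = "fracture_assessment")
}

#' @export
print.fracture_assessment <- function(x, ...) {
  cat(sprintf("Fracture assessment: J = %.3g J/m^2 vs J_a = %.3g J/m^2 -> %s\n",
              x$J, x$J_a, x$regime))
  invisible(x)
}
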