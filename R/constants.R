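#' Empirical and model constants
#'
#' All fixed numerical constants used by the transport models, collected in
#' one place. The pressure-flow and tissue-resistance-pressure correlations
#' are empirical fits taken from ex vivo porcine tissue experiments; the
#' `1.27` factor belongs to the tunnelling-crack energy-release relation
#' J = P^2 h / (1.27 E). `2.96*pi` and `31.08` are the compact-form
#' permeability constants, algebraically equal to `4*pi*0.74` and `23/0.74`.
#'
#' @format A named list:
#' \describe{
#'   \item{pressure_slope}{0.74 kPa per (uL/s) — slope of the applied-pressure
#'     correlation p = 0.74 q + 23.}
#'   \item{pressure_intercept}{23 kPa — intercept of the same correlation.}
#'   \item{trp_slope}{10.4 kPa per (mL/min) — slope of the tissue resistance
#'     pressure relation TRP = 10.4 q + 1.14.}
#'   \item{trp_intercept}{1.14 kPa — intercept of the TRP relation.}
#'   \item{fracture_factor}{1.27 — dimensionless factor in the fracture
#'     toughness relation.}
#'   \item{compact_k_factor}{2.96*pi — combined constant 4*pi*0.74 in the
#'     compact permeability form.}
#'   \item{compact_k_shift}{31.08 uL/s — combined constant 23/0.74 in the
#'     compact permeability form.}
#' }
#' @export
depot_constants <- list(
  pressure_slope     = 0.74,
  pressure_intercept = 23,
  trp_slope          = 10.4,
  trp_intercept      = 1.14,
  fracture_factor    = 1.27,
  compact_k_factor   = 2.96 * pi,
  compact_k_shift    = 23 / 0.74
)

# Detector full scale for 16-bit stacks written/read by this package.
.DEPOT_MAX_COUNT <- 65535
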