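#' Injection protocol
#'
#' Describes how the drug solution is administered: volumetric flow rate,
#' total injected volume, delivery mode, the needle-tip position on the
#' detector and the frame interval of the accompanying radiograph stack.
#' The infusion duration `T = total_volume / flow_rate` is derived.
#'
#' @param flow_rate volumetric flow rate in uL/min (must be > 0).
#' @param total_volume total injected volume Q in uL (must be > 0).
#' @param mode `"continuous"` (pump infusion) or `"single_shot"` (bolus).
#' @param needle_tip integer vector `c(row, col)` of the needle-tip pixel.
#' @param frame_interval time between consecutive radiograph frames, s.
#' @return An object of class `"injection_protocol"`.
#' @examples
#' injection_protocol(flow_rate = 25, total_volume = 500)
#' @export
injection_protocol <- function(flow_rate, total_volume,
                               mode = c("continuous", "single_shot"),
                               needle_tip = c(1, 1),
                               frame_interval = 60) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(flow_rate), length(flow_rate) == 1,
            is.numeric(total_volume), length(total_volume) == 1,
            length(needle_tip) == 2, frame_interval > 0)
  if (flow_rate <= 0) stop("flow_rate must be > 0 (uL/min)")
  if (total_volume <= 0) stop("total_volume must be > 0 (uL)")
  structure(list(
    flow_rate = flow_rate,            # uL/min
    total_volume = total_volume,      # uL
    mode = mode,
    needle_tip = as.numeric(needle_tip),
    frame_interval = frame_interval,  # s
    duration = 60 * total_volume / flow_rate  # s
  ), class = "injection_protocol")
}

#' @export
print.injection_protocol <- function(x, ...) {
  cat("Injection protocol (", x$mode, ")\n", sep = "")
  cat(sprintf("  flow rate     : %g uL/min\n", x$flow_rate))
  cat(sprintf("  total volume  : %g uL\n", x$total_volume))
  cat(sprintf("  duration      : %g s\n", x$duration))
  cat(sprintf("  needle tip    : (%g, %g) [row, col]\n",
              x$needle_tip[1], x$needle_tip[2]))
  invisible(x)
}

#' Tissue and solution parameters
#'
#' Physical parameters of the tissue and of the injected solution used by
#' the transport models and the simulator.
#'
#' @param epsilon effective volume fraction of the solution within the depot
#'   (dimensionless, in (0, 1]). The depot volume balance is
#'   `epsilon * (4/3) * pi * WF^3 = q * t`; `epsilon = 1` means the depot is
#'   entirely solution.
#' @param anisotropy ratio of the vertical to the horizontal depot semi-axis
#'   (dimensionless, > 0); 1 gives a spherical depot.
#' @param crack_width assumed micro-crack width h in um (default 800).
#' @param youngs_modulus tissue Young's modulus E in kPa. The default 1.01 kPa
#'   is the value jointly consistent (least squares) with the two reference
#'   pressure/toughness pairs (23.3 kPa, 340 J/m^2) and (94 kPa, 5.5 kJ/m^2)
#'   at h = 800 um.
#' @param fracture_threshold critical fracture toughness J_a in J/m^2
#'   (default 4100, i.e. 4.1 kJ/m^2 for subcutaneous tissue).
#' @param lag_volume dead volume V_lag in uL that accumulates at the needle
#'   tip before solution first appears in the tissue (onset lag model).
#' @param mu_abs linear absorption coefficient of the drug solution, 1/mm.
#' @return An object of class `"tissue_parameters"`.
#' @examples
#' tissue_parameters()                      # defaults
#' tissue_parameters(anisotropy = 0.73)     # horizontally elongated depot
#' @export
tissue_parameters <- function(epsilon = 1.0, anisotropy = 1.0,
                              crack_width = 800, youngs_modulus = 1.01,
                              fracture_threshold = 4100,
                              lag_volume = 100, mu_abs = 1.0) {
  if (!(epsilon > 0 && epsilon <= 1)) stop("epsilon must be in (0, 1]")
  if (anisotropy <= 0) stop("anisotropy must be > 0")
  if (crack_width <= 0 || youngs_modulus <= 0 || fracture_threshold <= 0 ||
      mu_abs <= 0) {
    stop("crack_width, youngs_modulus, fracture_threshold and mu_abs must be > 0")
  }
  if (lag_volume < 0) stop("lag_volume must be >= 0")
  structure(list(
    epsilon = epsilon,
    anisotropy = anisotropy,
    crack_width = crack_width,          # um
    youngs_modulus = youngs_modulus,    # kPa
    fracture_threshold = fracture_threshold,  # J/m^2
    lag_volume = lag_volume,            # uL
    mu_abs = mu_abs                     # 1/mm
  ), class = "tissue_parameters")
}

#' @export
print.tissue_parameters <- function(x, ...) {
  cat("Tissue/solution parameters\n")
  cat(sprintf("  epsilon (volume fraction) : %g\n", x$epsilon))
  cat(sprintf("  anisotropy (a_v/a_h)      : %g\n", x$anisotropy))
  cat(sprintf("  crack width h             : %g um\n", x$crack_width))
  cat(sprintf("  Young's modulus E         : %g kPa\n", x$youngs_modulus))
  cat(sprintf("  fracture threshold J_a    : %g J/m^2\n", x$fracture_threshold))
  cat(sprintf("  lag volume V_lag          : %g uL\n", x$lag_volume))
  cat(sprintf("  mu_abs                    : %g 1/mm\n", x$mu_abs))
  invisible(x)
}
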