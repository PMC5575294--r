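#' Convert a volumetric flow rate between units
#'
#' The empirical correlations in this package were fitted with flow in
#' specific units (uL/s for the applied-pressure correlation, mL/min for the
#' tissue-resistance-pressure relation) while the Darcy estimator works in
#' SI. All public functions take an explicit `flow_unit` argument and convert
#' through this helper.
#'
#' @param q numeric vector of flow rates.
#' @param from,to units, one of `"uL/s"`, `"uL/min"`, `"mL/min"`, `"m3/s"`.
#' @return numeric vector of flow rates in the `to` unit.
#' @examples
#' convert_flow(25, "uL/min", "uL/s")   # 0.41667
#' convert_flow(6, "mL/min", "m3/s")    # 1e-7
#' @export
convert_flow <- function(q, from = "uL/min", to = "m3/s") {
  stopifnot(is.numeric(q))
  # factors to m^3/s
  to_si <- c("uL/s" = 1e-9, "uL/min" = 1e-9 / 60,
             "mL/min" = 1e-6 / 60, "m3/s" = 1)
  from <- match.arg(from, names(to_si))
  to <- match.arg(to, names(to_si))
  q * to_si[[from]] / to_si[[to]]
}
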