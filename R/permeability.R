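#' Estimate directional Darcy permeability from a wetting-front trace
#'
#' Applies the point-source Darcy estimator `k = q / (4 pi p r_t)` to the
#' measured end-of-infusion wetting front in each direction, with the
#' applied pressure taken from the empirical pressure-flow correlation
#' ([injection_pressure()]) unless supplied. The last usable
#' injection-region sample provides the depot radii.
#'
#' @param trace a [wf_trace()] in mm.
#' @param protocol an [injection_protocol()].
#' @param pressure applied pressure, kPa; default
#'   `injection_pressure(q)` at the protocol flow rate.
#' @param tissue_label free-text label carried into reports.
#' @return An object of class `"permeability_estimate"`: list with
#'   `k_horizontal`, `k_vertical` (m^4/(N s)), `pressure` (kPa),
#'   `radius_used` (named, m), `flow_rate` (uL/min) and `tissue`.
#' @examples
#' pr <- injection_protocol(25, 500)
#' t <- seq(60, 1200, 60)
#' wf <- 4.924 * (25 * t / 60 / 500)^(1/3)
#' tr <- wf_trace(t, wf, wf, rep("IR", length(t)))
#' estimate_permeability(tr, pr)
#' @export
estimate_permeability <- function(trace, protocol, pressure = NULL,
                                  tissue_label = "tissue") {
  stopifnot(inherits(protocol, "injection_protocol"))
  ir <- trace[trace$region == "IR" & is.finite(trace$wf_h) &
              is.finite(trace$wf_v) & trace$wf_h > 0 & trace$wf_v > 0, ,
              drop = FALSE]
  if (nrow(ir) == 0) stop("no usable injection-region samples")
  last <- ir[nrow(ir), ]
  if (is.null(pressure)) {
    pressure <- injection_pressure(protocol$flow_rate, "uL/min")
  }
  r_h <- last$wf_h / 1000  # mm -> m
  r_v <- last$wf_v / 1000
  structure(list(
    k_horizontal = permeability_darcy(protocol$flow_rate, r_h, pressure),
    k_vertical = permeability_darcy(protocol$flow_rate, r_v, pressure),
    pressure = pressure,
    radius_used = c(horizontal = r_h, vertical = r_v),
    flow_rate = protocol$flow_rate,
    tissue = tissue_label
  ), class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  cat("Darcy point-source permeability estimate (", x$tissue, ")\n",
      sep = "")
  cat(sprintf("  flow rate : %g uL/min, pressure %.3g kPa\n",
              x$flow_rate, x$pressure))
  cat(sprintf("  k_horizontal : %.3e m^4/(N s)  (r_t = %.3g mm)\n",
              x$k_horizontal, 1000 * x$radius_used[["horizontal"]]))
  cat(sprintf("  k_vertical   : %.3e m^4/(N s)  (r_t = %.3g mm)\n",
              x$k_vertical, 1000 * x$radius_used[["vertical"]]))
  invisible(x)
}

#' @export
as.data.frame.permeability_estimate <- function(x, ...) {
  data.frame(tissue = x$tissue, flow_rate = x$flow_rate,
             k_horizontal = x$k_horizontal, k_vertical = x$k_vertical)
}
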