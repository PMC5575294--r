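#' Fit the cube-root depot growth law to a measured wetting-front trace
#'
#' During infusion the wetting front of a spherical depot grows as
#' `WF(t) = WF_m * (q t / Q)^(1/3)`, where `WF_m` is the front radius at the
#' end of infusion. This fits the single free scale `WF_m` to a measured
#' trace by least squares on WF, then reports the goodness of fit R^2 on the
#' normalized trace `R(t) = WF(t)/WF_m` against the model `(q t / Q)^(1/3)`.
#'
#' Only injection-region (`"IR"`) samples are used: after the end of
#' infusion the growth law no longer applies.
#'
#' @param trace a [wf_trace()] data frame (columns `time`, `wf_h`, `wf_v`,
#'   `region`), or any data frame with a `time` column and the chosen
#'   front column.
#' @param protocol an [injection_protocol()] supplying `q` and `Q`.
#' @param direction which front to fit, `"horizontal"` (`wf_h`) or
#'   `"vertical"` (`wf_v`).
#' @param region samples to use; default `"IR"`.
#' @return An object of class `"wf_fit"`: list with `wf_max` (fitted WF_m,
#'   in the units of the trace, mm), `r_squared`, `fitted`, `residuals`,
#'   `data`, `protocol` and `direction`. A constant or decreasing trace is
#'   flagged degenerate with a warning (R^2 still reported).
#' @examples
#' pr <- injection_protocol(25, 500, frame_interval = 60)
#' t <- seq(60, 1200, by = 60)
#' wf <- 4.924 * (25 * t / 60 / 500)^(1/3)
#' fit <- fit_normalized_wf(data.frame(time = t, wf_h = wf), pr)
#' coef(fit)          # WF_m ~ 4.924 mm
#' summary(fit)
#' @export
fit_normalized_wf <- function(trace, protocol,
                              direction = c("horizontal", "vertical"),
                              region = "IR") {
  direction <- match.arg(direction)
  col <- if (direction == "horizontal") "wf_h" else "wf_v"
  stopifnot(is.data.frame(trace), "time" %in% names(trace))
  if (!col %in% names(trace)) stop("trace lacks column ", col)
  d <- trace
  if ("region" %in% names(d)) d <- d[d$region %in% region, , drop = FALSE]
  d <- d[is.finite(d$time) & is.finite(d[[col]]), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 finite samples in region ", region)
  if (any(diff(d$time) <= 0)) stop("times must be strictly increasing")

  t <- d$time
  y <- d[[col]]
  x <- normalized_wf(protocol$flow_rate, t, protocol$total_volume)

  degenerate <- FALSE
  if (stats::sd(y) == 0 || stats::cor(t, y) <= 0) {
    degenerate <- TRUE
    warning("degenerate wetting-front trace (constant or decreasing); ",
            "fit reported anyway")
  }

  # least squares on WF with WF_m the only free parameter
  wf_max <- sum(x * y) / sum(x^2)
  fitted <- wf_max * x
  res <- y - fitted

  # R^2 on the normalized trace
  r_meas <- y / wf_max
  ss_res <- sum((r_meas - x)^2)
  ss_tot <- sum((r_meas - mean(r_meas))^2)
  r2 <- if (ss_tot == 0) -Inf else 1 - ss_res / ss_tot

  structure(list(
    wf_max = wf_max,
    r_squared = r2,
    fitted = fitted,
    residuals = res,
    data = data.frame(time = t, wf = y, model = x),
    protocol = protocol,
    direction = direction,
    degenerate = degenerate
  ), class = "wf_fit")
}

#' @export
print.wf_fit <- function(x, ...) {
  cat("Cube-root depot growth fit (", x$direction, " front)\n", sep = "")
  cat(sprintf("  WF_m = %.4g mm,  R^2 = %.4f%s\n", x$wf_max, x$r_squared,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' @export
summary.wf_fit <- function(object, ...) {
  cat("Cube-root depot growth fit WF(t) = WF_m * (q t / Q)^(1/3)\n")
  cat(sprintf("  direction : %s\n", object$direction))
  cat(sprintf("  n samples : %d (IR)\n", nrow(object$data)))
  cat(sprintf("  WF_m      : %.4g mm\n", object$wf_max))
  cat(sprintf("  R^2       : %.4f\n", object$r_squared))
  cat(sprintf("  residuals : RMS %.3g mm, max |r| %.3g mm\n",
              sqrt(mean(object$residuals^2)), max(abs(object$residuals))))
  invisible(object)
}

#' @export
coef.wf_fit <- function(object, ...) c(wf_max = object$wf_max)

#' @export
residuals.wf_fit <- function(object, ...) object$residuals

#' @export
fitted.wf_fit <- function(object, ...) object$fitted

#' Predict the wetting front at new times from a fitted growth law
#'
#' @param object a `"wf_fit"`.
#' @param newdata optional data frame with a `time` column (s); defaults to
#'   the fitted times.
#' @param ... unused.
#' @return predicted WF in mm, capped at `WF_m` beyond the end of infusion
#'   (the growth law only applies while infusing).
#' @export
predict.wf_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  pr <- object$protocol
  r <- pmin(normalized_wf(pr$flow_rate, t, pr$total_volume), 1)
  object$wf_max * r
}

#' @export
plot.wf_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$model, d$wf / x$wf_max,
                 xlab = "model (q t / Q)^(1/3)",
                 ylab = "measured WF / WF_m",
                 main = sprintf("Normalized WF fit, R^2 = %.3f", x$r_squared),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
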