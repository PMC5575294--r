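#' Wetting-front trace
#'
#' Per-frame horizontal and vertical wetting-front distances from the
#' needle tip, with each sample labelled as injection region (`"IR"`,
#' during infusion) or diffusion region (`"DR"`, after the pump stops).
#'
#' @param time times, s.
#' @param wf_h,wf_v front distances, mm (`NA` where no front detected).
#' @param region character vector of `"IR"`/`"DR"` labels.
#' @param pixel_size pixel pitch, um (kept as attribute).
#' @param needle_tip `c(row, col)` (kept as attribute).
#' @return data frame of class `"wf_trace"`.
#' @export
wf_trace <- function(time, wf_h, wf_v, region,
                     pixel_size = NA_real_, needle_tip = c(NA, NA)) {
  stopifnot(length(time) == length(wf_h), length(wf_h) == length(wf_v),
            length(region) == length(time))
  if (any(wf_h < 0, na.rm = TRUE) || any(wf_v < 0, na.rm = TRUE)) {
    stop("wetting-front distances must be >= 0")
  }
  out <- data.frame(time = time, wf_h = wf_h, wf_v = wf_v,
                    region = as.character(region))
  attr(out, "pixel_size") <- pixel_size
  attr(out, "needle_tip") <- needle_tip
  class(out) <- c("wf_trace", "data.frame")
  out
}

#' Detect the wetting front along an intensity profile
#'
#' Finds the outermost distance at which a (median-smoothed) profile still
#' exceeds a threshold placed a fraction `frac` of the way between the
#' noise floor and the profile peak. The outermost crossing is used so
#' plateaus and interior dips do not truncate the front.
#'
#' @param profile data frame with `distance` (mm) and a value column
#'   (`rcs` or the first non-distance column).
#' @param noise_floor background level of the profile (default 0).
#' @param frac threshold fraction above the noise floor (default 0.1).
#' @param smooth odd window for median smoothing (default 3; 1 = none).
#' @return front distance in mm, or `NA` (no front) if the profile never
#'   exceeds the threshold.
#' @export
detect_wf <- function(profile, noise_floor = 0, frac = 0.1, smooth = 3) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 1)
  vcol <- setdiff(names(profile), "distance")[1]
  v <- profile[[vcol]]
  v[is.na(v)] <- noise_floor
  if (smooth > 1 && length(v) > smooth) v <- stats::runmed(v, smooth)
  peak <- max(v)
  if (peak <= noise_floor) return(NA_real_)
  thr <- noise_floor + frac * (peak - noise_floor)
  idx <- which(v >= thr)
  if (length(idx) == 0) return(NA_real_)
  profile$distance[max(idx)]
}

# Thin line profile (median over a band of rows/cols) outward from needle.
line_profile <- function(map, needle_tip, direction, side, band,
                         pixel_size) {
  r0 <- round(needle_tip[1]); c0 <- round(needle_tip[2])
  hb <- band %/% 2
  if (direction == "horizontal") {
    rows <- max(1, r0 - hb):min(nrow(map), r0 + hb)
    cols <- if (side == "right") c0:ncol(map) else c0:1
    vals <- apply(map[rows, cols, drop = FALSE], 2, stats::median,
                  na.rm = TRUE)
  } else {
    cols <- max(1, c0 - hb):min(ncol(map), c0 + hb)
    rows <- if (side == "down") r0:nrow(map) else r0:1
    vals <- apply(map[rows, cols, drop = FALSE], 1, stats::median,
                  na.rm = TRUE)
  }
  data.frame(distance = (seq_along(vals) - 1) * pixel_size / 1000,
             rcs = vals)
}

#' Track the wetting front through a corrected stack
#'
#' For each frame of a flat-field-corrected (and, if needed, registered)
#' transmission stack, computes the RCS map against a pre-onset baseline
#' frame and locates the horizontal and vertical wetting fronts from thin
#' line profiles through the needle tip ([detect_wf()]). Horizontal fronts
#' are taken as the outermost of the left/right sides; the vertical front
#' is tracked downward (into the tissue). Samples acquired while the pump
#' is running (`t <= Q/q`) are labelled `"IR"`, later ones `"DR"`.
#'
#' @param stack [image_stack()] of transmission frames.
#' @param protocol [injection_protocol()] (needle tip, flow, volume).
#' @param tissue [tissue_parameters()] (supplies `mu_abs`).
#' @param baseline_index frame used as the pre-injection baseline.
#' @param noise_floor passed to [detect_wf()]; the default `NULL`
#'   estimates it per profile as median + 5 MAD, which rejects pure-noise
#'   profiles before onset.
#' @param band width (pixels) of the median band of the line profiles.
#' @return a [wf_trace()]; frames with no detectable front give `NA`.
#' @export
track_wf <- function(stack, protocol, tissue, baseline_index = 1,
                     noise_floor = NULL, band = 3) {
  stopifnot(inherits(stack, "image_stack"),
            inherits(protocol, "injection_protocol"),
            inherits(tissue, "tissue_parameters"))
  baseline <- stack$frames[[baseline_index]]
  nt <- protocol$needle_tip
  px <- stack$pixel_size
  n <- length(stack$frames)
  wf_h <- wf_v <- rep(NA_real_, n)
  # noise scale of an RCS map from its (background) corner patches
  corner_sigma <- function(m, frac = 0.1) {
    kr <- max(2, round(frac * nrow(m)))
    kc <- max(2, round(frac * ncol(m)))
    v <- c(m[1:kr, 1:kc], m[1:kr, (ncol(m) - kc + 1):ncol(m)],
           m[(nrow(m) - kr + 1):nrow(m), 1:kc],
           m[(nrow(m) - kr + 1):nrow(m), (ncol(m) - kc + 1):ncol(m)])
    stats::sd(v[is.finite(v)])
  }
  for (i in seq_len(n)) {
    m <- rcs_map(stack$frames[[i]], baseline, tissue$mu_abs)
    fl <- noise_floor
    if (is.null(fl)) {
      fl <- 5 * corner_sigma(m)
      # no depot signal at the needle itself -> no front in this frame
      ctr <- central_rcs(list(m), nt, half_width = 2)
      if (!is.finite(ctr) || ctr <= fl) next
    }
    h_r <- detect_wf(line_profile(m, nt, "horizontal", "right", band, px),
                     fl)
    h_l <- detect_wf(line_profile(m, nt, "horizontal", "left", band, px),
                     fl)
    hh <- suppressWarnings(max(h_r, h_l, na.rm = TRUE))
    wf_h[i] <- if (is.finite(hh)) hh else NA_real_
    wf_v[i] <- detect_wf(line_profile(m, nt, "vertical", "down", band, px),
                         fl)
  }
  region <- ifelse(stack$timestamps <= protocol$duration, "IR", "DR")
  wf_trace(stack$timestamps, wf_h, wf_v, region,
           pixel_size = px, needle_tip = nt)
}

#' Depot aspect ratio over a region of a wetting-front trace
#'
#' Mean and standard deviation of `WF_v / WF_h` over the samples of the
#' requested region. A ratio near 1 indicates a spherical depot; below 1,
#' preferential horizontal spreading.
#'
#' @param trace a [wf_trace()].
#' @param region `"IR"` or `"DR"`.
#' @return list with `mean`, `sd` (across frames; `NA` if a single frame)
#'   and `n`. Samples with `wf_h = 0` or missing fronts are skipped with a
#'   warning.
#' @export
aspect_ratio <- function(trace, region = c("IR", "DR")) {
  region <- match.arg(region)
  d <- trace[trace$region == region, , drop = FALSE]
  if (nrow(d) == 0) stop("no samples in region ", region)
  usable <- is.finite(d$wf_h) & is.finite(d$wf_v) & d$wf_h > 0
  if (any(!usable)) {
    warning(sum(!usable), " sample(s) with missing or zero horizontal ",
            "front skipped")
  }
  d <- d[usable, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable samples in region ", region)
  ratio <- d$wf_v / d$wf_h
  list(mean = mean(ratio), sd = stats::sd(ratio), n = nrow(d),
       region = region)
}

#' Onset time of solution appearance
#'
#' First time at which the needle-adjacent RCS rises above the baseline
#' mean plus `k_sigma` baseline standard deviations, sustained for
#' `sustain` consecutive frames. Models the observed lag before solution
#' first appears in the tissue.
#'
#' @param times frame times, s.
#' @param values central RCS series (e.g. from [central_rcs()]).
#' @param baseline_window number of initial frames treated as pre-onset
#'   baseline (>= 3).
#' @param k_sigma threshold multiplier (default 3).
#' @param sustain consecutive frames required above threshold (default 3).
#' @return onset time in s, or `NA` if the threshold is never sustained.
#' @export
onset_time <- function(times, values, baseline_window = 3, k_sigma = 3,
                       sustain = 3) {
  stopifnot(length(times) == length(values))
  if (baseline_window < 3) stop("need at least 3 baseline frames")
  if (length(values) <= baseline_window) stop("series shorter than baseline")
  base <- values[seq_len(baseline_window)]
  thr <- mean(base) + k_sigma * stats::sd(base)
  above <- values > thr
  above[seq_len(baseline_window)] <- FALSE
  n <- length(values)
  for (i in which(above)) {
    if (i + sustain - 1 <= n && all(above[i:(i + sustain - 1)])) {
      return(times[i])
    }
    # allow a shorter run at the very end of the series
    if (i + sustain - 1 > n && all(above[i:n])) return(times[i])
  }
  NA_real_
}

#' Quasi-saturation time of a wetting-front trace
#'
#' Earliest time after which the relative wetting-front change
#' `(max - min) / max` within every subsequent sliding window stays below
#' `rel_tol`, i.e. the front has stopped distinguishably advancing.
#'
#' @param trace a [wf_trace()] or data frame with `time`, `wf_h`, `wf_v`.
#' @param rel_tol relative tolerance (default 0.01, i.e. 1%).
#' @param window sliding window length, s (default 60).
#' @param direction `"both"` (default; both fronts must settle),
#'   `"horizontal"` or `"vertical"`.
#' @return quasi-saturation time in s, or `NA` if never reached within the
#'   trace.
#' @export
quasi_saturation_time <- function(trace, rel_tol = 0.01, window = 60,
                                  direction = c("both", "horizontal",
                                                "vertical")) {
  direction <- match.arg(direction)
  t <- trace$time
  if (max(t) - min(t) < window) stop("trace shorter than the window")
  cols <- switch(direction, both = c("wf_h", "wf_v"),
                 horizontal = "wf_h", vertical = "wf_v")
  usable <- t + window <= max(t)
  idx <- which(usable)
  relrange <- vapply(idx, function(i) {
    sel <- t >= t[i] & t <= t[i] + window
    max(vapply(cols, function(cl) {
      v <- trace[[cl]][sel]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(Inf)
      mx <- max(v)
      if (mx == 0) 0 else (mx - min(v)) / mx
    }, numeric(1)))
  }, numeric(1))
  ok <- relrange < rel_tol
  # earliest index from which every later window also satisfies the bound
  good <- rev(cumprod(rev(ok))) > 0
  if (!any(good)) return(NA_real_)
  t[idx[which(good)[1]]]
}
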