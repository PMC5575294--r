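#' Relative solution content (RCS) map of a frame
#'
#' Path-integrated amount of injected solution per pixel along the beam,
#' recovered from attenuation relative to a pre-injection baseline:
#' `RCS = log(baseline / frame) / mu_abs` (mm of solution). Negative values
#' (noise) are clipped to 0; non-positive or masked pixels in either input
#' propagate as `NA`.
#'
#' @param frame transmission matrix at the time of interest.
#' @param baseline pre-injection (pre-onset) transmission matrix.
#' @param mu_abs linear absorption coefficient of the solution, 1/mm.
#' @return RCS matrix, mm of solution path length per pixel.
#' @export
rcs_map <- function(frame, baseline, mu_abs) {
  stopifnot(is.matrix(frame), is.matrix(baseline),
            all(dim(frame) == dim(baseline)))
  if (mu_abs <= 0) stop("mu_abs must be > 0")
  bad <- (!is.na(frame) & frame <= 0) | (!is.na(baseline) & baseline <= 0)
  ratio <- baseline / frame
  ratio[bad] <- NA_real_
  out <- log(ratio) / mu_abs
  out[!is.na(out) & out < 0] <- 0
  out
}

#' Windowed RCS profile outward from the needle
#'
#' Averages the RCS map in a square sliding window (default 0.9 mm x
#' 0.9 mm) advancing pixel by pixel from the needle tip outward along the
#' chosen image axis, optionally normalized by the profile maximum.
#' For temporal comparisons across frames normalize jointly with
#' [rcs_profile_series()] instead.
#'
#' @param map RCS matrix from [rcs_map()].
#' @param needle_tip `c(row, col)` needle-tip pixel.
#' @param direction `"horizontal"` (along columns, rightward) or
#'   `"vertical"` (along rows, downward).
#' @param pixel_size pixel pitch, um.
#' @param window_mm window side, mm (default 0.9).
#' @param normalize divide by the profile maximum (default `TRUE`).
#' @return data frame with `distance` (mm from needle) and `rcs`.
#' @export
rcs_profile <- function(map, needle_tip,
                        direction = c("horizontal", "vertical"),
                        pixel_size = 9, window_mm = 0.9, normalize = TRUE) {
  direction <- match.arg(direction)
  w <- max(1L, round(window_mm * 1000 / pixel_size))
  if (w > min(dim(map))) stop("window larger than frame")
  r0 <- round(needle_tip[1]); c0 <- round(needle_tip[2])
  if (r0 < 1 || r0 > nrow(map) || c0 < 1 || c0 > ncol(map)) {
    stop("needle_tip outside frame")
  }
  half <- w %/% 2
  if (r0 - half < 1 || r0 + half > nrow(map) ||
      c0 - half < 1 || c0 + half > ncol(map)) {
    warning("needle near frame border; windows truncated")
  }
  n_steps <- if (direction == "horizontal") ncol(map) - c0 else nrow(map) - r0
  d <- 0:n_steps
  vals <- vapply(d, function(k) {
    if (direction == "horizontal") {
      rows <- max(1, r0 - half):min(nrow(map), r0 + half)
      cols <- max(1, c0 + k - half):min(ncol(map), c0 + k + half)
    } else {
      rows <- max(1, r0 + k - half):min(nrow(map), r0 + k + half)
      cols <- max(1, c0 - half):min(ncol(map), c0 + half)
    }
    mean(map[rows, cols], na.rm = TRUE)
  }, numeric(1))
  if (normalize) {
    m <- max(vals, na.rm = TRUE)
    if (is.finite(m) && m > 0) vals <- vals / m
  }
  data.frame(distance = d * pixel_size / 1000, rcs = vals)
}

#' RCS profiles over time, jointly normalized
#'
#' Computes [rcs_profile()] for each frame of a list of RCS maps and
#' normalizes all profiles by the single global maximum over the whole
#' sequence, so values at different times share one scale.
#'
#' @param maps list of RCS matrices (one per time point).
#' @param times numeric vector of times, s.
#' @inheritParams rcs_profile
#' @return data frame with `time`, `distance` and `rcs` in `[0, 1]`.
#' @export
rcs_profile_series <- function(maps, times, needle_tip,
                               direction = c("horizontal", "vertical"),
                               pixel_size = 9, window_mm = 0.9) {
  direction <- match.arg(direction)
  stopifnot(length(maps) == length(times))
  profs <- lapply(maps, rcs_profile, needle_tip = needle_tip,
                  direction = direction, pixel_size = pixel_size,
                  window_mm = window_mm, normalize = FALSE)
  gmax <- max(vapply(profs, function(p) max(p$rcs, na.rm = TRUE), numeric(1)))
  out <- do.call(rbind, Map(function(p, t) {
    if (is.finite(gmax) && gmax > 0) p$rcs <- p$rcs / gmax
    cbind(time = t, p)
  }, profs, times))
  rownames(out) <- NULL
  out
}

#' Temporal variation of an RCS profile
#'
#' Pointwise finite difference between two RCS profiles on the same
#' distance grid: `(RCS(t2) - RCS(t1)) / (t2 - t1)`. Positive values mean
#' the tissue at that distance is still taking up solution.
#'
#' @param profile_t1,profile_t2 data frames with `distance` and `rcs`.
#' @param t1,t2 the two times, s, `t2 > t1`.
#' @return data frame with `distance` and `rate` (1/s scale of the
#'   profile's units).
#' @export
rcs_temporal_variation <- function(profile_t1, profile_t2, t1, t2) {
  if (t2 <= t1) stop("t2 must be > t1")
  if (nrow(profile_t1) != nrow(profile_t2) ||
      any(abs(profile_t1$distance - profile_t2$distance) > 1e-9)) {
    stop("profiles must share the same distance grid")
  }
  data.frame(distance = profile_t1$distance,
             rate = (profile_t2$rcs - profile_t1$rcs) / (t2 - t1))
}

#' Mean RCS around the needle tip over time
#'
#' Helper for onset detection: mean RCS in a small box centred on the
#' needle tip, per frame.
#'
#' @param maps list of RCS matrices.
#' @param needle_tip `c(row, col)`.
#' @param half_width box half-width in pixels (default 5).
#' @return numeric vector, one value per map.
#' @export
central_rcs <- function(maps, needle_tip, half_width = 5) {
  r0 <- round(needle_tip[1]); c0 <- round(needle_tip[2])
  vapply(maps, function(m) {
    rows <- max(1, r0 - half_width):min(nrow(m), r0 + half_width)
    cols <- max(1, c0 - half_width):min(ncol(m), c0 + half_width)
    mean(m[rows, cols], na.rm = TRUE)
  }, numeric(1))
}
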