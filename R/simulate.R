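#' Detector model for the synthetic radiograph renderer
#'
#' Parameters of the simulated detector: mean gain (counts at full
#' transmission) and dark offset with per-pixel fixed-pattern variation,
#' Poisson shot noise on the photon signal, Gaussian read noise, an
#' optional smooth tissue-texture attenuation field that drifts with the
#' sample, and integer quantization of counts.
#'
#' @param gain_mean mean full-transmission signal, counts.
#' @param gain_pattern_sd relative sd of the per-pixel fixed gain pattern.
#' @param offset_mean mean dark offset, counts.
#' @param offset_pattern_sd relative sd of the fixed offset pattern.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param poisson apply Poisson shot noise to the photon signal.
#' @param n_gain_frames number of gain (flat) exposures to simulate.
#' @param texture_sd sd of the tissue-texture optical depth (0 = none).
#' @param texture_scale_px correlation length of the texture, px.
#' @param quantize round counts to integers and clamp to 16-bit range.
#' @return list of class `"detector_model"`.
#' @export
detector_model <- function(gain_mean = 30000, gain_pattern_sd = 0.02,
                           offset_mean = 1000, offset_pattern_sd = 0.05,
                           read_noise_sd = 50, poisson = TRUE,
                           n_gain_frames = 10, texture_sd = 0,
                           texture_scale_px = 8, quantize = TRUE) {
  stopifnot(gain_mean > 0, offset_mean >= 0, read_noise_sd >= 0,
            gain_pattern_sd >= 0, offset_pattern_sd >= 0, texture_sd >= 0,
            n_gain_frames >= 1)
  structure(list(gain_mean = gain_mean, gain_pattern_sd = gain_pattern_sd,
                 offset_mean = offset_mean,
                 offset_pattern_sd = offset_pattern_sd,
                 read_noise_sd = read_noise_sd, poisson = poisson,
                 n_gain_frames = n_gain_frames, texture_sd = texture_sd,
                 texture_scale_px = texture_scale_px, quantize = quantize),
            class = "detector_model")
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles everything needed to simulate one injection experiment:
#' protocol, tissue/solution parameters, detector model, detector
#' geometry, frame schedule, sample-drift schedule and the RNG seed.
#' Defaults mirror the reference acquisition: 9 um pixels and a
#' 36.0 mm x 24.0 mm field of view.
#'
#' @param protocol an [injection_protocol()].
#' @param tissue a [tissue_parameters()].
#' @param detector a [detector_model()].
#' @param dims frame dimensions `c(rows, cols)`; default the full
#'   36 x 24 mm field at 9 um (2667 x 4000).
#' @param pixel_size pixel pitch, um.
#' @param frame_times frame schedule, s (strictly increasing). Default:
#'   from 0 to 1.25 x infusion duration at the protocol frame interval.
#' @param drift sample drift schedule: `NULL` (none), a function
#'   `t -> c(dr, dc)` in pixels, or a data frame with `time`, `dr`, `dc`
#'   (linearly interpolated).
#' @param front_rim_mm width of the linear concentration taper at the
#'   depot rim; 0 gives a sharp front.
#' @param dr_relax_h,dr_relax_v power-law exponents for post-infusion
#'   front relaxation per direction (`a(t) = a(T) (t/T)^exponent`);
#'   0 freezes the front after infusion.
#' @param seed RNG seed; mandatory whenever any noise source is active.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(protocol, tissue, detector = detector_model(),
                            dims = c(2667, 4000), pixel_size = 9,
                            frame_times = NULL, drift = NULL,
                            front_rim_mm = 0, dr_relax_h = 0,
                            dr_relax_v = 0, seed = NULL) {
  stopifnot(inherits(protocol, "injection_protocol"),
            inherits(tissue, "tissue_parameters"),
            inherits(detector, "detector_model"),
            length(dims) == 2, all(dims >= 8), pixel_size > 0)
  if (is.null(frame_times)) {
    frame_times <- seq(0, 1.25 * protocol$duration,
                       by = protocol$frame_interval)
  }
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  stochastic <- detector$read_noise_sd > 0 || detector$poisson ||
    detector$gain_pattern_sd > 0 || detector$offset_pattern_sd > 0 ||
    detector$texture_sd > 0
  if (stochastic && is.null(seed)) {
    stop("seed is mandatory when any stochastic component is active")
  }
  structure(list(protocol = protocol, tissue = tissue, detector = detector,
                 dims = as.integer(dims), pixel_size = pixel_size,
                 frame_times = frame_times, drift = drift,
                 front_rim_mm = front_rim_mm, dr_relax_h = dr_relax_h,
                 dr_relax_v = dr_relax_v,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic injection scenario\n")
  cat(sprintf("  %g uL at %g uL/min (T = %g s), %d frames, %d x %d px @ %g um\n",
              x$protocol$total_volume, x$protocol$flow_rate,
              x$protocol$duration, length(x$frame_times),
              x$dims[1], x$dims[2], x$pixel_size))
  invisible(x)
}

# drift schedule -> c(dr, dc) at time t, pixels
drift_at <- function(drift, t) {
  if (is.null(drift)) return(c(0, 0))
  if (is.function(drift)) return(drift(t))
  c(stats::approx(drift$time, drift$dr, t, rule = 2)$y,
    stats::approx(drift$time, drift$dc, t, rule = 2)$y)
}

#' Simulate depot growth for a scenario
#'
#' Ground-truth ellipsoidal depot kinematics. Until the injected volume
#' reaches the dead volume `V_lag` the depot is absent; afterwards the
#' semi-axes satisfy the volume balance
#' `epsilon * (4/3) pi a_h^2 a_v = V_injected - V_lag` at a fixed axis
#' ratio `a_v / a_h = anisotropy`. After the end of infusion the front is
#' frozen by default, or relaxed by a configurable power law.
#'
#' @param config a [scenario_config()].
#' @return data frame of class `"depot_state_series"` with `time` (s),
#'   `a_h`, `a_v` (mm), `injected` and `depot` volumes (uL) and `onset`
#'   (logical).
#' @export
simulate_depot <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  pr <- config$protocol
  ts <- config$tissue
  t <- config$frame_times
  injected <- pmin(pr$flow_rate * pmax(t, 0) / 60, pr$total_volume)
  depot <- pmax(injected - ts$lag_volume, 0)
  # a_h^3 * anisotropy * (4/3) pi eps = V  (m^3)
  a_h <- (3 * depot * 1e-9 /
            (4 * pi * ts$epsilon * ts$anisotropy))^(1 / 3) * 1000  # mm
  a_v <- ts$anisotropy * a_h
  post <- t > pr$duration
  if (any(post) && (config$dr_relax_h != 0 || config$dr_relax_v != 0)) {
    f <- (t[post] / pr$duration)
    a_h[post] <- a_h[post] * f^config$dr_relax_h
    a_v[post] <- a_v[post] * f^config$dr_relax_v
  }
  out <- data.frame(time = t, a_h = a_h, a_v = a_v,
                    injected = injected, depot = depot, onset = depot > 0)
  class(out) <- c("depot_state_series", "data.frame")
  out
}

# smooth random field with ~scale_px correlation length, unit sd
smooth_field <- function(dims, scale_px) {
  m <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  if (scale_px > 1) {
    k <- rep(1, scale_px)
    sm_rows <- apply(m, 2, function(col)
      stats::filter(col, k / scale_px, circular = TRUE))
    m <- t(apply(sm_rows, 1, function(row)
      stats::filter(row, k / scale_px, circular = TRUE)))
    m <- (m - mean(m)) / stats::sd(m)
  }
  m
}

# per-pixel fixed patterns of the detector (photon gain G and offset O)
make_detector_patterns <- function(detector, dims) {
  G <- detector$gain_mean *
    (1 + detector$gain_pattern_sd * matrix(stats::rnorm(prod(dims)),
                                           dims[1], dims[2]))
  G[G < 1] <- 1
  O <- detector$offset_mean *
    (1 + detector$offset_pattern_sd * matrix(stats::rnorm(prod(dims)),
                                             dims[1], dims[2]))
  O[O < 0] <- 0
  list(gain = G, offset = O)
}

# bilinear crop of a canvas; sample content displaced by (dr, dc), i.e.
# sampling at origin - drift moves the content down/right with the sample
crop_bilinear <- function(canvas, dims, origin, dr, dc) {
  r <- origin[1] - dr + seq_len(dims[1]) - 1
  c <- origin[2] - dc + seq_len(dims[2]) - 1
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  canvas[r0, c0] * outer(1 - fr, 1 - fc) +
    canvas[r0 + 1, c0] * outer(fr, 1 - fc) +
    canvas[r0, c0 + 1] * outer(1 - fr, fc) +
    canvas[r0 + 1, c0 + 1] * outer(fr, fc)
}

# analytic chord-length map (mm) through an ellipsoid with beam-axis
# semi-axis equal to a_h (horizontal rotational symmetry)
ellipsoid_chord <- function(a_h, a_v, center, dims, pixel_size,
                            rim_mm = 0) {
  if (a_h <= 0 || a_v <= 0) return(matrix(0, dims[1], dims[2]))
  px_mm <- pixel_size / 1000
  dy <- (seq_len(dims[1]) - center[1]) * px_mm
  dx <- (seq_len(dims[2]) - center[2]) * px_mm
  rho2 <- outer(dy^2 / a_v^2, dx^2 / a_h^2, `+`)
  chord <- 2 * a_h * sqrt(pmax(1 - rho2, 0))
  if (rim_mm > 0) {
    w <- rim_mm / a_h
    conc <- pmin(pmax((1 - sqrt(rho2)) / w, 0), 1)
    chord <- chord * conc
  }
  chord
}

#' Render one parallel-projection radiograph of a depot state
#'
#' Forward model for a single frame: the analytic chord length through the
#' ellipsoidal depot attenuates the beam by the Beer-Lambert law, the
#' detector applies its fixed gain/offset patterns, then shot noise, read
#' noise and quantization. Noise is drawn from the current RNG state; seed
#' management belongs to the caller ([generate_stack()] seeds once per
#' stack).
#'
#' @param state list or one-row data frame with `a_h`, `a_v` (mm).
#' @param config a [scenario_config()].
#' @param patterns detector patterns from an earlier call (list with
#'   `gain`, `offset`); generated on the fly if `NULL`.
#' @param drift_px `c(dr, dc)` sample drift of this frame, pixels.
#' @param texture optional texture optical-depth matrix (already drifted).
#' @return numeric matrix of detector counts.
#' @export
render_projection <- function(state, config, patterns = NULL,
                              drift_px = c(0, 0), texture = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  det <- config$detector
  dims <- config$dims
  if (is.null(patterns)) patterns <- make_detector_patterns(det, dims)
  center <- config$protocol$needle_tip + drift_px
  chord <- ellipsoid_chord(state$a_h, state$a_v, center, dims,
                           config$pixel_size, config$front_rim_mm)
  depth <- config$tissue$mu_abs * chord
  if (!is.null(texture)) depth <- depth + texture
  photon <- patterns$gain * exp(-depth)
  if (det$poisson) {
    photon <- matrix(stats::rpois(length(photon), photon),
                     dims[1], dims[2])
  }
  counts <- photon + patterns$offset
  if (det$read_noise_sd > 0) {
    counts <- counts + stats::rnorm(length(counts), 0, det$read_noise_sd)
  }
  if (det$quantize) counts <- pmin(pmax(round(counts), 0), .DEPOT_MAX_COUNT)
  counts
}

#' Generate a complete synthetic radiograph stack with ground truth
#'
#' Runs the depot simulation, renders one frame per schedule entry
#' (applying the drift schedule), simulates the flat-field calibration
#' exposures (`n_gain_frames` gain images and offset images with the same
#' noise model), and records every generator parameter in a truth
#' manifest. Identical config + seed reproduce the stack bit for bit.
#'
#' @param config a [scenario_config()].
#' @return list with `stack` ([image_stack()]), `depot`
#'   (the [simulate_depot()] series), `flats` (list of `gain_frames`,
#'   `offset_frames`), `patterns` (noiseless detector patterns) and
#'   `truth` (manifest list of all parameters incl. per-frame drift).
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.na(config$seed)) set.seed(config$seed)
  det <- config$detector
  dims <- config$dims
  patterns <- make_detector_patterns(det, dims)

  # flat-field calibration exposures (no sample)
  one_exposure <- function(signal) {
    if (det$poisson) {
      signal <- matrix(stats::rpois(length(signal), signal),
                       dims[1], dims[2])
    }
    counts <- signal + patterns$offset
    if (det$read_noise_sd > 0) {
      counts <- counts + stats::rnorm(length(counts), 0, det$read_noise_sd)
    }
    if (det$quantize) {
      counts <- pmin(pmax(round(counts), 0), .DEPOT_MAX_COUNT)
    }
    counts
  }
  gain_frames <- lapply(seq_len(det$n_gain_frames),
                        function(i) one_exposure(patterns$gain))
  dark <- function() {
    counts <- patterns$offset
    if (det$read_noise_sd > 0) {
      counts <- counts + stats::rnorm(length(counts), 0, det$read_noise_sd)
    }
    if (det$quantize) {
      counts <- pmin(pmax(round(counts), 0), .DEPOT_MAX_COUNT)
    }
    counts
  }
  offset_frames <- lapply(seq_len(det$n_gain_frames), function(i) dark())

  # sample texture canvas, sampled per frame at the drifted position
  max_drift <- 0
  if (!is.null(config$drift)) {
    dr <- vapply(config$frame_times,
                 function(t) drift_at(config$drift, t), numeric(2))
    max_drift <- ceiling(max(abs(dr))) + 2
  }
  texture_canvas <- NULL
  if (det$texture_sd > 0) {
    pad <- max_drift + 2
    texture_canvas <- det$texture_sd *
      smooth_field(dims + 2 * pad, det$texture_scale_px)
    texture_origin <- c(pad + 1, pad + 1)
  }

  depot <- simulate_depot(config)
  frames <- vector("list", nrow(depot))
  drift_rec <- matrix(0, nrow(depot), 2, dimnames = list(NULL, c("dr", "dc")))
  for (i in seq_len(nrow(depot))) {
    d <- drift_at(config$drift, depot$time[i])
    drift_rec[i, ] <- d
    texture <- NULL
    if (!is.null(texture_canvas)) {
      texture <- crop_bilinear(texture_canvas, dims, texture_origin,
                               d[1], d[2])
    }
    frames[[i]] <- render_projection(depot[i, ], config, patterns,
                                     drift_px = d, texture = texture)
  }
  stack <- image_stack(frames, depot$time, pixel_size = config$pixel_size)
  truth <- list(
    seed = config$seed,
    flow_rate = config$protocol$flow_rate,
    total_volume = config$protocol$total_volume,
    duration = config$protocol$duration,
    needle_tip = config$protocol$needle_tip,
    epsilon = config$tissue$epsilon,
    anisotropy = config$tissue$anisotropy,
    lag_volume = config$tissue$lag_volume,
    mu_abs = config$tissue$mu_abs,
    pixel_size = config$pixel_size,
    dims = dims,
    front_rim_mm = config$front_rim_mm,
    onset_time = if (any(depot$onset)) min(depot$time[depot$onset])
                 else NA_real_,
    final_a_h = depot$a_h[nrow(depot)],
    final_a_v = depot$a_v[nrow(depot)],
    drift = drift_rec
  )
  list(stack = stack, depot = depot,
       flats = list(gain_frames = gain_frames,
                    offset_frames = offset_frames),
       patterns = patterns, truth = truth)
}
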