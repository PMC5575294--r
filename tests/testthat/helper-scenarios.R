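# Small synthetic scenarios used across the suite. 50 um pixels and
# ~160 px frames keep full renders fast while depots span tens of pixels.

noiseless_detector <- function(n_gain = 2) {
  detector_model(gain_pattern_sd = 0, offset_pattern_sd = 0,
                 read_noise_sd = 0, poisson = FALSE,
                 n_gain_frames = n_gain, quantize = FALSE)
}

small_protocol <- function(flow_rate = 100, total_volume = 40,
                           needle = c(80, 80), interval = 2) {
  injection_protocol(flow_rate, total_volume, needle_tip = needle,
                     frame_interval = interval)
}

small_scenario <- function(flow_rate = 100, total_volume = 40,
                           lag_volume = 10, anisotropy = 1,
                           noiseless = FALSE, seed = 1,
                           dims = c(160, 160), pixel_size = 50,
                           frame_times = seq(0, 30, 2), ...) {
  pr <- small_protocol(flow_rate, total_volume,
                       needle = round(dims / 2),
                       interval = diff(frame_times[1:2]))
  ti <- tissue_parameters(lag_volume = lag_volume, anisotropy = anisotropy,
                          mu_abs = 1)
  det <- if (noiseless) noiseless_detector() else detector_model()
  scenario_config(pr, ti, det, dims = dims, pixel_size = pixel_size,
                  frame_times = frame_times,
                  seed = if (noiseless) NULL else seed, ...)
}

# simulate + flat-field correct; returns sim plus transmission stack
corrected_sim <- function(config) {
  sim <- generate_stack(config)
  flat <- flat_field_set(sim$flats$gain_frames, sim$flats$offset_frames)
  trans <- image_stack(lapply(sim$stack$frames, flat_field_correct,
                              flat = flat),
                       sim$stack$timestamps,
                       pixel_size = config$pixel_size)
  sim$trans <- trans
  sim$flat <- flat
  sim
}

# analytic ellipsoid chord map, independent oracle for render/RCS tests
chord_oracle <- function(a_h, a_v, center, dims, pixel_size) {
  px_mm <- pixel_size / 1000
  dy <- (seq_len(dims[1]) - center[1]) * px_mm
  dx <- (seq_len(dims[2]) - center[2]) * px_mm
  rho2 <- outer(dy^2 / a_v^2, dx^2 / a_h^2, `+`)
  2 * a_h * sqrt(pmax(1 - rho2, 0))
}
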