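test_that("depot kinematics satisfy the volume balance at every step", {
  for (ar in c(1, 0.73, 1.4)) for (eps in c(1, 0.6)) {
    pr <- injection_protocol(100, 60, needle_tip = c(40, 40),
                             frame_interval = 5)
    ti <- tissue_parameters(epsilon = eps, anisotropy = ar,
                            lag_volume = 10, mu_abs = 1)
    cfg <- scenario_config(pr, ti, noiseless_detector(), dims = c(64, 64),
                           pixel_size = 50, frame_times = seq(0, 50, 5))
    d <- simulate_depot(cfg)
    lhs <- eps * (4 / 3) * pi * (d$a_h * 1e-3)^2 * (d$a_v * 1e-3) * 1e9
    expect_equal(lhs, d$depot, tolerance = 1e-9)
    expect_equal(d$a_v[d$onset] / d$a_h[d$onset],
                 rep(ar, sum(d$onset)))
    expect_true(all(d$injected <= pr$total_volume + 1e-12))
  }
})

test_that("an isotropic depot reaches the closed-form spherical radius", {
  pr <- injection_protocol(25, 500, frame_interval = 60)
  ti <- tissue_parameters(epsilon = 1, anisotropy = 1, lag_volume = 0,
                          mu_abs = 1)
  cfg <- scenario_config(pr, ti, noiseless_detector(), dims = c(64, 64),
                         frame_times = seq(0, 1200, 60))
  d <- simulate_depot(cfg)
  expect_equal(d$a_h[nrow(d)], 4.9237, tolerance = 1e-4)   # mm
  expect_equal(d$a_h, d$a_v)
})

test_that("the onset flag first turns on when the dead volume is spent", {
  pr <- injection_protocol(100, 500, frame_interval = 10)
  ti <- tissue_parameters(lag_volume = 100, mu_abs = 1)
  cfg <- scenario_config(pr, ti, noiseless_detector(), dims = c(64, 64),
                         frame_times = seq(0, 120, 10))
  d <- simulate_depot(cfg)
  expect_equal(min(d$time[d$onset]), 70)      # first frame after 60 s lag
  expect_false(any(d$onset[d$time <= 60]))
})

test_that("rendered central transmission matches the analytic chord", {
  cfg <- small_scenario(noiseless = TRUE, dims = c(64, 64),
                        frame_times = c(0, 20))
  sim <- generate_stack(cfg)
  a <- sim$depot$a_h[2]
  center <- cfg$protocol$needle_tip
  frame <- sim$stack$frames[[2]]
  trans <- (frame - sim$patterns$offset) / sim$patterns$gain
  expect_equal(trans[center[1], center[2]],
               exp(-cfg$tissue$mu_abs * 2 * a), tolerance = 1e-12)
})

test_that("a zero depot renders as gain + offset", {
  cfg <- small_scenario(noiseless = TRUE, dims = c(32, 32),
                        frame_times = c(0, 5), lag_volume = 1000)
  sim <- generate_stack(cfg)
  expect_equal(sim$stack$frames[[2]],
               sim$patterns$gain + sim$patterns$offset)
})

test_that("identical config and seed reproduce the stack bit for bit", {
  cfg <- small_scenario(seed = 99, dims = c(48, 48),
                        frame_times = c(0, 5, 10))
  s1 <- generate_stack(cfg)
  s2 <- generate_stack(cfg)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$flats, s2$flats)
  s3 <- generate_stack(small_scenario(seed = 100, dims = c(48, 48),
                                      frame_times = c(0, 5, 10)))
  expect_false(identical(s1$stack$frames, s3$stack$frames))
})

test_that("render noise variance matches the configured level", {
  # read-noise-only detector; variance across repeated renders ~ sd^2
  det <- detector_model(gain_pattern_sd = 0, offset_pattern_sd = 0,
                        read_noise_sd = 40, poisson = FALSE,
                        n_gain_frames = 1, quantize = FALSE)
  pr <- injection_protocol(100, 40, needle_tip = c(8, 8),
                           frame_interval = 5)
  ti <- tissue_parameters(lag_volume = 0, mu_abs = 1)
  cfg <- scenario_config(pr, ti, det, dims = c(16, 16), pixel_size = 50,
                         frame_times = c(0, 10), seed = 1)
  state <- list(a_h = 0.3, a_v = 0.3)
  set.seed(123)
  patterns <- list(gain = matrix(30000, 16, 16),
                   offset = matrix(1000, 16, 16))
  renders <- replicate(120, render_projection(state, cfg, patterns),
                       simplify = FALSE)
  arr <- simplify2array(renders)
  pixel_var <- apply(arr, c(1, 2), var)
  expect_equal(mean(pixel_var), 40^2, tolerance = 0.1)
})

test_that("generated stacks honour the schedule and metadata defaults", {
  pr <- injection_protocol(100, 40, needle_tip = c(16, 16),
                           frame_interval = 5)
  ti <- tissue_parameters(lag_volume = 0, mu_abs = 1)
  times <- c(0, 3, 9, 27)
  cfg <- scenario_config(pr, ti, noiseless_detector(), dims = c(32, 32),
                         frame_times = times)
  sim <- generate_stack(cfg)
  expect_length(sim$stack$frames, length(times))
  expect_equal(sim$stack$timestamps, times)
  expect_equal(scenario_config(pr, ti, noiseless_detector(),
                               dims = c(32, 32),
                               frame_times = times)$pixel_size, 9)
})

test_that("a stochastic scenario without a seed is rejected", {
  pr <- injection_protocol(100, 40, needle_tip = c(16, 16),
                           frame_interval = 5)
  ti <- tissue_parameters(mu_abs = 1)
  expect_error(scenario_config(pr, ti, detector_model(), dims = c(32, 32),
                               frame_times = c(0, 5)),
               "seed is mandatory")
})

test_that("the smooth-front option tapers but never exceeds the sharp chord", {
  cfg_sharp <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                              frame_times = c(0, 20))
  cfg_soft <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                             frame_times = c(0, 20), front_rim_mm = 0.4)
  sharp <- generate_stack(cfg_sharp)
  soft <- generate_stack(cfg_soft)
  # more attenuation path in the sharp case everywhere
  expect_true(all(soft$stack$frames[[2]] >= sharp$stack$frames[[2]] - 1e-9))
  expect_gt(sum(soft$stack$frames[[2]] > sharp$stack$frames[[2]] + 1e-9), 0)
})
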