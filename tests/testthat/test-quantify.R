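test_that("RCS maps are zero without change and match the chord oracle", {
  base <- matrix(runif(100, 0.5, 1), 10, 10)
  expect_equal(rcs_map(base, base, 1), matrix(0, 10, 10))
  # rendered depot vs analytic ellipsoid chord
  cfg <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                        frame_times = c(0, 20))
  sim <- corrected_sim(cfg)
  m <- rcs_map(sim$trans$frames[[2]], sim$trans$frames[[1]],
               cfg$tissue$mu_abs)
  chord <- chord_oracle(sim$depot$a_h[2], sim$depot$a_v[2],
                        cfg$protocol$needle_tip, cfg$dims, cfg$pixel_size)
  expect_lt(max(abs(m - chord)) / max(chord), 0.02)
  # masking propagates
  b2 <- base; b2[2, 2] <- 0
  expect_true(is.na(rcs_map(base, b2, 1)[2, 2]))
})

test_that("a pure-noise frame has near-zero median RCS", {
  set.seed(31)
  base <- matrix(30000, 40, 40)
  noisy <- base + matrix(rnorm(1600, 0, 60), 40, 40)
  m <- rcs_map(noisy / base, base / base, 1)
  expect_lt(median(m), 3 * 60 / 30000)
})

test_that("RCS profiles are normalized, monotone for a sphere, validated", {
  uni <- matrix(2.5, 60, 60)
  p <- rcs_profile(uni, c(30, 30), "horizontal", pixel_size = 50,
                   window_mm = 0.9)
  expect_equal(p$rcs, rep(1, nrow(p)))
  # spherical depot: profile nonincreasing with distance
  cfg <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                        frame_times = c(0, 20))
  sim <- corrected_sim(cfg)
  m <- rcs_map(sim$trans$frames[[2]], sim$trans$frames[[1]], 1)
  pr <- rcs_profile(m, cfg$protocol$needle_tip, "vertical",
                    pixel_size = 50, window_mm = 0.9)
  expect_true(all(diff(pr$rcs) <= 1e-9))
  expect_error(rcs_profile(uni, c(30, 30), pixel_size = 50,
                           window_mm = 10), "window larger")
  expect_warning(rcs_profile(uni, c(2, 2), pixel_size = 50,
                             window_mm = 0.9), "truncated")
  expect_error(rcs_profile(uni, c(300, 30), pixel_size = 50),
               "outside frame")
})

test_that("RCS temporal variation is a finite difference and nonnegative while filling", {
  d <- data.frame(distance = 0:5, rcs = c(5, 4, 3, 2, 1, 0))
  expect_equal(rcs_temporal_variation(d, d, 0, 10)$rate, rep(0, 6))
  d2 <- d; d2$rcs <- d$rcs + 3
  expect_equal(rcs_temporal_variation(d, d2, 0, 10)$rate, rep(0.3, 6))
  expect_error(rcs_temporal_variation(d, d2, 10, 10), "t2 must be")
  expect_error(rcs_temporal_variation(d, d2[1:3, ], 0, 10), "distance grid")
  # noiseless filling sequence: nonnegative inside the wetting front
  cfg <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                        frame_times = c(0, 10, 20))
  sim <- corrected_sim(cfg)
  m1 <- rcs_map(sim$trans$frames[[2]], sim$trans$frames[[1]], 1)
  m2 <- rcs_map(sim$trans$frames[[3]], sim$trans$frames[[1]], 1)
  p1 <- rcs_profile(m1, cfg$protocol$needle_tip, "horizontal",
                    pixel_size = 50, normalize = FALSE)
  p2 <- rcs_profile(m2, cfg$protocol$needle_tip, "horizontal",
                    pixel_size = 50, normalize = FALSE)
  v <- rcs_temporal_variation(p1, p2, 10, 20)
  inside <- v$distance <= sim$depot$a_h[3]
  expect_true(all(v$rate[inside] >= -1e-9))
})

test_that("front detection finds steps, rejects flat profiles, hits semi-axes", {
  step <- data.frame(distance = seq(0, 5, 0.1),
                     rcs = as.numeric(seq(0, 5, 0.1) <= 2.5))
  expect_equal(detect_wf(step), 2.5)
  expect_true(is.na(detect_wf(data.frame(distance = 0:9,
                                         rcs = rep(0, 10)))))
  # rendered ellipsoid: semi-axis recovered within 2 px
  cfg <- small_scenario(noiseless = TRUE, dims = c(96, 96),
                        frame_times = c(0, 20), anisotropy = 0.8)
  sim <- corrected_sim(cfg)
  m <- rcs_map(sim$trans$frames[[2]], sim$trans$frames[[1]], 1)
  ph <- rcs_profile(m, cfg$protocol$needle_tip, "horizontal",
                    pixel_size = 50, window_mm = 0.15, normalize = FALSE)
  px_mm <- cfg$pixel_size / 1000
  expect_lt(abs(detect_wf(ph) - sim$depot$a_h[2]), 2 * px_mm)
})

test_that("tracked fronts are symmetric, monotone and grow as t^(1/3)", {
  cfg <- small_scenario(noiseless = TRUE, lag_volume = 0,
                        frame_times = seq(0, 24, 2))
  sim <- corrected_sim(cfg)
  tr <- track_wf(sim$trans, cfg$protocol, cfg$tissue)
  ir <- tr[tr$region == "IR" & is.finite(tr$wf_h), ]
  px_mm <- cfg$pixel_size / 1000
  expect_true(all(abs(ir$wf_h - ir$wf_v) <= 2 * px_mm))
  expect_true(all(diff(ir$wf_h) >= -1e-9))
  # log-log slope of the injection-region front vs time
  fitlm <- lm(log(wf_h) ~ log(time), data = ir[ir$time > 0, ])
  expect_equal(unname(coef(fitlm)[2]), 1 / 3, tolerance = 0.15)
  expect_lt(abs(unname(coef(fitlm)[2]) - 1 / 3), 0.05)
})

test_that("aspect ratio is recovered, scale-invariant and validated", {
  t <- seq(2, 20, 2)
  tr <- wf_trace(t, 2 * t^(1/3), 2 * t^(1/3), rep("IR", length(t)))
  expect_equal(aspect_ratio(tr, "IR")$mean, 1)
  # scale invariance
  tr2 <- wf_trace(t, 6 * t^(1/3), 6 * t^(1/3) * 0.8, rep("IR", length(t)))
  tr3 <- wf_trace(t, 3 * t^(1/3), 3 * t^(1/3) * 0.8, rep("IR", length(t)))
  expect_equal(aspect_ratio(tr2, "IR")$mean, aspect_ratio(tr3, "IR")$mean)
  expect_error(aspect_ratio(tr, "DR"), "no samples")
  trz <- wf_trace(c(1, 2, 3), c(0, 1, 1), c(1, 1, 1), rep("IR", 3))
  expect_warning(a <- aspect_ratio(trz, "IR"), "skipped")
  expect_equal(a$n, 2)
})

test_that("generator anisotropy is recovered from tracked fronts", {
  cfg <- small_scenario(anisotropy = 0.73, seed = 11,
                        frame_times = seq(0, 24, 2))
  sim <- corrected_sim(cfg)
  tr <- track_wf(sim$trans, cfg$protocol, cfg$tissue)
  a <- suppressWarnings(aspect_ratio(tr, "IR"))
  expect_lt(abs(a$mean - 0.73), 0.05)
})

test_that("onset time equals dead volume over flow rate", {
  # V_lag = 100 uL at q = 100 uL/min -> 60 s
  pr <- injection_protocol(100, 500, needle_tip = c(48, 48),
                           frame_interval = 10)
  ti <- tissue_parameters(lag_volume = 100, mu_abs = 1)
  cfg <- scenario_config(pr, ti, detector_model(), dims = c(96, 96),
                         pixel_size = 50, frame_times = seq(0, 120, 10),
                         seed = 21)
  sim <- corrected_sim(cfg)
  maps <- lapply(sim$trans$frames, rcs_map,
                 baseline = sim$trans$frames[[1]], mu_abs = 1)
  ot <- onset_time(sim$trans$timestamps,
                   central_rcs(maps, pr$needle_tip))
  expect_lte(abs(ot - 60), 10)
  # V_lag = 0: onset at the first post-start frame
  ti0 <- tissue_parameters(lag_volume = 0, mu_abs = 1)
  cfg0 <- scenario_config(pr, ti0, detector_model(), dims = c(96, 96),
                          pixel_size = 50, frame_times = seq(0, 120, 10),
                          seed = 22)
  sim0 <- corrected_sim(cfg0)
  maps0 <- lapply(sim0$trans$frames, rcs_map,
                  baseline = sim0$trans$frames[[1]], mu_abs = 1)
  vals0 <- central_rcs(maps0, pr$needle_tip)
  # the baseline window must predate filling for a V_lag = 0 series;
  # synthesize one with three true pre-start frames
  expect_equal(onset_time(c(-20, -10, 0, sim0$trans$timestamps[-1]),
                          c(0, 0, 0, vals0[-1]), baseline_window = 3),
               10)
  # threshold never exceeded -> no onset
  expect_true(is.na(onset_time(1:10, rep(0, 10))))
  expect_error(onset_time(1:10, rep(0, 10), baseline_window = 2),
               "at least 3")
})

test_that("quasi-saturation is found once the front stops advancing", {
  t <- seq(0, 300, 10)
  const <- wf_trace(t, rep(2, length(t)), rep(2, length(t)),
                    rep("DR", length(t)))
  expect_equal(quasi_saturation_time(const), 0)
  grow <- wf_trace(t[-1], 2 * t[-1]^(1/3), 2 * t[-1]^(1/3),
                   rep("IR", length(t) - 1))
  expect_true(is.na(quasi_saturation_time(grow, window = 60)))
  # plateau at 120 s: QS within one window of the true time
  wf <- pmin(2 * (t / 120)^(1/3), 2)
  plateau <- wf_trace(t, wf, wf, ifelse(t <= 120, "IR", "DR"))
  qs <- quasi_saturation_time(plateau, rel_tol = 0.01, window = 60)
  expect_lte(abs(qs - 120), 60)
  expect_error(quasi_saturation_time(const[1:3, ], window = 60),
               "shorter than the window")
})

test_that("ROI statistics use the population sigma and flag degenerate means", {
  st <- image_stack(list(matrix(4, 10, 10),
                         matrix(c(1, 3), 10, 10),
                         matrix(0, 10, 10)), c(0, 1, 2))
  roi <- list(rows = c(1, 10), cols = c(1, 10))
  cv <- roi_cv(st, roi)
  expect_equal(cv$cv[1], 0)
  expect_equal(cv$cv[2], 0.5)          # population sigma of {1,3}/mean 2
  expect_true(is.na(cv$cv[3]))         # zero mean is undefined
  expect_error(roi_cv(st, list(rows = c(1, 11), cols = c(1, 10))),
               "outside frame")
})

test_that("standard ROIs sit on the needle and first fronts at 0.9 mm size", {
  t <- c(10, 20, 30)
  tr <- wf_trace(t, c(1, 1.5, 2), c(0.9, 1.2, 1.6), rep("IR", 3))
  rois <- define_rois(c(500, 500), tr, dims = c(1000, 1000),
                      pixel_size = 9, size_mm = 0.9)
  expect_named(rois, c("SC", "SWF_h", "SWF_v"))
  expect_equal(rois$SC$center, c(500, 500))
  # 0.9 mm at 9 um = 100 px wide boxes
  expect_equal(diff(rois$SC$rows) + 1, 101)
  expect_equal(rois$SWF_h$center[2] - 500, round(1 / 0.009))
  expect_equal(rois$SWF_v$center[1] - 500, round(0.9 / 0.009))
  expect_warning(define_rois(c(30, 30), tr, dims = c(200, 200),
                             pixel_size = 9), "clipped")
  none <- wf_trace(t, rep(NA_real_, 3), rep(NA_real_, 3), rep("IR", 3))
  expect_error(define_rois(c(500, 500), none, dims = c(1000, 1000)),
               "no post-onset")
})

test_that("C_v near the first front decays as solution spreads in", {
  cfg <- small_scenario(noiseless = TRUE, lag_volume = 5,
                        frame_times = seq(0, 24, 2), front_rim_mm = 0.3)
  sim <- corrected_sim(cfg)
  tr <- track_wf(sim$trans, cfg$protocol, cfg$tissue)
  rois <- suppressWarnings(
    define_rois(cfg$protocol$needle_tip, tr, cfg$dims,
                pixel_size = cfg$pixel_size))
  cv <- roi_cv(sim$trans, rois)
  swf <- cv[cv$roi == "SWF_h", ]
  first_on <- which(is.finite(tr$wf_h))[1]
  expect_lt(swf$cv[nrow(swf)], swf$cv[first_on])
})

test_that("total RCS mass is nondecreasing during infusion", {
  cfg <- small_scenario(noiseless = TRUE, frame_times = seq(0, 24, 2))
  sim <- corrected_sim(cfg)
  mass <- vapply(sim$trans$frames, function(f) {
    sum(rcs_map(f, sim$trans$frames[[1]], 1), na.rm = TRUE)
  }, numeric(1))
  ir <- sim$trans$timestamps <= cfg$protocol$duration
  expect_true(all(diff(mass[ir]) >= -1e-9))
})

test_that("Darcy estimate from tracked fronts matches the generator equivalent", {
  cfg <- small_scenario(noiseless = TRUE, frame_times = seq(0, 24, 2))
  sim <- corrected_sim(cfg)
  tr <- track_wf(sim$trans, cfg$protocol, cfg$tissue)
  est <- estimate_permeability(tr, cfg$protocol)
  p <- injection_pressure(cfg$protocol$flow_rate, "uL/min")
  k_true <- permeability_darcy(cfg$protocol$flow_rate,
                               sim$truth$final_a_h / 1000, p)
  expect_lt(abs(est$k_horizontal - k_true) / k_true, 0.1)
})
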