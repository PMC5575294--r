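test_that("pressure correlation evaluates and validates its domain", {
  expect_equal(injection_pressure(25, "uL/min"), 23.30833, tolerance = 1e-6)
  expect_equal(injection_pressure(0), 23)
  expect_equal(injection_pressure(100, "uL/min"), 24.23333,
               tolerance = 1e-6)
  expect_error(injection_pressure(-1), "non-negative")
})

test_that("tissue resistance pressure matches the linear relation", {
  expect_equal(round(tissue_resistance_pressure(0.025), 1), 1.4)
  expect_equal(tissue_resistance_pressure(0.1), 2.18, tolerance = 1e-9)
  expect_equal(tissue_resistance_pressure(0), 1.14)
  expect_equal(tissue_resistance_pressure(100, "uL/min"),
               tissue_resistance_pressure(0.1))
  expect_error(tissue_resistance_pressure(-0.1), "non-negative")
})

test_that("radial point-source velocity follows inverse-square scaling", {
  expect_equal(radial_velocity(4 * pi, 1), 1)
  expect_equal(radial_velocity(1, 2), radial_velocity(1, 1) / 4)
  expect_equal(radial_velocity(4.1667e-10, 4.924e-3), 1.3676e-6,
               tolerance = 1e-4)
  expect_error(radial_velocity(1, 0), "r must be")
})

test_that("Darcy permeability matches brute-force SI arithmetic", {
  # oracle: convert everything to SI by hand and divide
  q_si <- 25 * 1e-9 / 60
  k_oracle <- q_si / (4 * pi * 23.308 * 1000 * 4.924e-3)
  expect_equal(permeability_darcy(25, 4.924e-3, 23.308), k_oracle)
  expect_equal(k_oracle, 2.889e-13, tolerance = 1e-3)
  expect_equal(permeability_darcy(25, 4.924e-3, 2 * 23.308),
               k_oracle / 2)
  expect_error(permeability_darcy(0, 1e-3, 10), "must all be > 0")
  expect_error(permeability_darcy(25, -1, 10), "must all be > 0")
})

test_that("compact permeability form agrees with the SI form on a grid", {
  qs <- exp(seq(log(10), log(10000), length.out = 7))     # uL/min
  rs <- seq(1e-3, 20e-3, length.out = 7)                  # m
  for (q in qs) for (r in rs) {
    p <- injection_pressure(q, "uL/min")
    expect_equal(permeability_compact(q, r),
                 permeability_darcy(q, r, p), tolerance = 1e-6)
  }
})

test_that("permeability is invariant to the flow unit supplied", {
  p <- injection_pressure(25, "uL/min")
  k1 <- permeability_darcy(25, 4.9e-3, p, flow_unit = "uL/min")
  k2 <- permeability_darcy(25 / 60, 4.9e-3, p, flow_unit = "uL/s")
  k3 <- permeability_darcy(0.025, 4.9e-3, p, flow_unit = "mL/min")
  expect_equal(k1, k2)
  expect_equal(k1, k3)
})

test_that("spherical wetting front follows the cube-root volume balance", {
  # 500 uL at epsilon = 1: WF_m = (3 * 5e-7 / 4 pi)^(1/3) = 4.924 mm
  expect_equal(wf_spherical(25, 1200, 1), 4.9237e-3, tolerance = 1e-4)
  expect_equal(wf_spherical(25, 0), 0)
  expect_equal(wf_spherical(25, 600, epsilon = 1 / 8),
               2 * wf_spherical(25, 600, epsilon = 1))
  expect_error(wf_spherical(25, 100, epsilon = 0), "epsilon")
  expect_error(wf_spherical(25, -5), "t must be")
})

test_that("normalized wetting front has exact cube-root scaling", {
  expect_equal(normalized_wf(25, 1200, 500), 1)
  expect_equal(normalized_wf(25, 0, 500), 0)
  expect_equal(normalized_wf(25, 150, 500), 0.5)  # q t = Q / 8
  expect_error(normalized_wf(25, 100, 0), "Q must be")
  # monotone nondecreasing and R(8t) = 2 R(t)
  t <- seq(0, 1200, by = 7)
  r <- normalized_wf(25, t, 500)
  expect_true(all(diff(r) >= 0))
  t8 <- seq(1, 150, by = 3)
  expect_equal(normalized_wf(25, 8 * t8, 500),
               2 * normalized_wf(25, t8, 500))
})

test_that("fracture toughness reproduces reference operating points", {
  expect_equal(signif(fracture_toughness(23.3, 800, 1.01), 2), 340)
  expect_equal(signif(fracture_toughness(94, 800, 1.01) / 1000, 2), 5.5)
  # quadratic homogeneity in P
  J1 <- fracture_toughness(10, 800, 1.01)
  for (a in c(2, 3.7, 9.4)) {
    expect_equal(fracture_toughness(a * 10, 800, 1.01), a^2 * J1)
  }
  expect_error(fracture_toughness(-1, 800, 1), "must all be > 0")
})

test_that("Young's modulus inversion round-trips the toughness relation", {
  for (P in c(10, 23.3, 94)) for (E in c(0.5, 1.01, 20)) {
    J <- fracture_toughness(P, 800, E)
    expect_equal(youngs_modulus_from_fracture(P, J, 800), E)
  }
})

test_that("fracture regime classification is threshold-inclusive", {
  expect_equal(assess_fracture(340, 4100)$regime, "no_fracture")
  expect_equal(assess_fracture(5500, 4100)$regime, "fracture")
  expect_equal(assess_fracture(4100, 4100)$regime, "fracture")
})

test_that("flow-unit conversion round-trips across units", {
  units <- c("uL/s", "uL/min", "mL/min", "m3/s")
  for (u in units) for (v in units) {
    expect_equal(convert_flow(convert_flow(3.7, u, v), v, u), 3.7)
  }
  expect_equal(convert_flow(25, "uL/min", "uL/s"), 25 / 60)
  expect_equal(convert_flow(6, "mL/min", "m3/s"), 1e-7)
})
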