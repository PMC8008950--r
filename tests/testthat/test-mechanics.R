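test_that("hoop stress follows the Laplace mean-wall form", {
  expect_equal(circumferential_stress(0, 188.76, 21.24), 0)
  # hand evaluation with the 0.133322 kPa/mmHg conversion
  expect_equal(circumferential_stress(100, 188.76, 21.24),
    100 * 0.133322 * 188.76 / 21.24,
    tolerance = 1e-12
  )
  expect_equal(circumferential_stress(100, 188.76, 21.24), 118.48,
    tolerance = 1e-4
  )
  # doubling the wall halves the stress
  expect_equal(
    circumferential_stress(100, 188.76, 2 * 21.24),
    circumferential_stress(100, 188.76, 21.24) / 2
  )
  expect_error(circumferential_stress(100, 188.76, 0),
    class = "arterymech_error_geometry"
  )
})

test_that("thin-wall hoop stress agrees with the thick-wall Lame mean", {
  # Lame solution for a pressurized thick-walled tube (zero outside
  # pressure): sigma_theta(r) = P ri^2 (ro^2 + r^2) / (r^2 (ro^2 - ri^2)).
  # Its wall-average equals P ri / h exactly (membrane identity), so the
  # two routes agree to integration accuracy.
  ri <- 188.76
  h <- 21.24
  ro <- ri + h
  p_kpa <- 100 * MMHG_TO_KPA
  lame_mean <- stats::integrate(
    function(r) p_kpa * ri^2 * (ro^2 + r^2) / (r^2 * (ro^2 - ri^2)),
    ri, ro
  )$value / h
  thin <- circumferential_stress(100, ri, h)
  expect_equal(thin, lame_mean, tolerance = 1e-6)
})

test_that("axial stress matches a capped-tube free-body oracle", {
  expect_equal(axial_stress(0, 0, 188.76, 21.24), 0)
  # oracle: total load = transducer force + pressure thrust on the cap,
  # divided by the numerically computed wall annulus area
  f_mn <- 2.0
  p_kpa <- 100 * MMHG_TO_KPA
  ri <- 188.76
  h <- 21.24
  area_mm2 <- (pi * (ri + h)^2 - pi * ri^2) * 1e-6
  oracle <- (f_mn + p_kpa * pi * ri^2 * 1e-6) / area_mm2
  expect_equal(axial_stress(f_mn, 100, ri, h), oracle, tolerance = 1e-12)
  expect_equal(axial_stress(f_mn, 100, ri, h), 131.25, tolerance = 1e-3)
})

test_that("pipeline stresses reproduce the simulator analytic stresses", {
  truth <- cached_truth()
  sol <- solve_equilibrium(
    truth$params, truth$unloaded,
    pressure_mmhg = seq(10, 140, 10), lambda_z = truth$ivs_true
  )
  analytic <- truth$stress_fn(sol$lambda_theta, sol$axial_stretch)
  st <- circumferential_stress(sol$pressure_mmHg, sol$r_i_um, sol$h_um)
  sz <- axial_stress(sol$force_mN, sol$pressure_mmHg, sol$r_i_um, sol$h_um)
  expect_equal(st, analytic$sigma_theta_kpa, tolerance = 1e-6)
  expect_equal(sz, analytic$sigma_z_kpa, tolerance = 1e-6)
})

test_that("stress values are invariant to the geometry length unit", {
  withr::local_seed(7)
  for (r in 1:20) {
    ri <- runif(1, 100, 400)
    h <- runif(1, 10, 60)
    p <- runif(1, 5, 150)
    f <- runif(1, 0.2, 8)
    expect_equal(
      circumferential_stress(p, ri, h),
      circumferential_stress(p, ri / 1000, h / 1000),
      tolerance = 1e-12
    )
    expect_equal(
      axial_stress(f, p, ri, h),
      axial_stress(f, p, ri / 1000, h / 1000, unit = "mm"),
      tolerance = 1e-12
    )
  }
})

test_that("stress-stretch curves are built per protocol context", {
  truth <- cached_truth()
  rec <- sample_recording(truth)
  geo <- default_unloaded_df(truth)
  circ <- build_stress_stretch(rec, geo, axis = "circumferential")
  expect_equal(nrow(circ), 15)
  expect_true(all(diff(circ$stretch) > 0))
  axial90 <- build_stress_stretch(rec, geo,
    axis = "axial",
    context_pressure = 90
  )
  expect_equal(nrow(axial90), 8)
  expect_true(all(axial90$context_pressure_mmHg == 90))
  # younger-animal protocol context is supported when recorded
  fl80 <- simulate_force_length_test(truth, pressures = 80, noise = FALSE) |>
    dplyr::mutate(test_type = "force_length", sample_id = "s1")
  axial80 <- build_stress_stretch(fl80, geo,
    axis = "axial",
    context_pressure = 80
  )
  expect_equal(nrow(axial80), 8)
  expect_error(
    build_stress_stretch(rec, geo, axis = "axial", context_pressure = 70),
    class = "arterymech_error_validation"
  )
  expect_error(
    build_stress_stretch(rec[rec$test_type == "force_length", ], geo,
      axis = "circumferential"
    ),
    class = "arterymech_error_validation"
  )
})

test_that("a stiffer artery gives a left-shifted circumferential curve", {
  ctrl <- artery_params("control")
  stiff <- artery_params("stiff")
  lt <- seq(1.2, 1.8, by = 0.01)
  s_ctrl <- wall_stress_analytic(ctrl, lt, 1.8)$sigma_theta_kpa
  s_stiff <- wall_stress_analytic(stiff, lt, 1.8)$sigma_theta_kpa
  # at matched stress, the stiff vessel sits at smaller stretch
  lo <- max(min(s_ctrl), min(s_stiff))
  hi <- min(max(s_ctrl), max(s_stiff))
  for (level in lo + c(0.2, 0.5, 0.8) * (hi - lo)) {
    lt_ctrl <- stats::approx(s_ctrl, lt, xout = level)$y
    lt_stiff <- stats::approx(s_stiff, lt, xout = level)$y
    expect_lt(lt_stiff, lt_ctrl)
  }
})

test_that("tangent modulus recovers exact slopes of linear curves", {
  cv <- data.frame(stretch = seq(1, 2, 0.1), stress_kpa = 3 + 7 * seq(1, 2, 0.1))
  for (m in c("window", "central")) {
    tm <- tangent_modulus(cv, method = m)
    expect_equal(tm$e_tan_kpa, rep(7, nrow(cv)), tolerance = 1e-10)
  }
  # invariance to row order
  shuf <- cv[sample(nrow(cv)), ]
  expect_equal(
    tangent_modulus(shuf, method = "window")$e_tan_kpa,
    tangent_modulus(cv, method = "window")$e_tan_kpa
  )
})

test_that("tangent modulus window auto-shrinks with a warning", {
  cv <- data.frame(stretch = c(1, 1.1, 1.2, 1.3), stress_kpa = c(1, 2, 4, 8))
  expect_warning(tangent_modulus(cv, window = 7), regexp = "shrunk")
  expect_error(tangent_modulus(cv[1:2, ]), class = "arterymech_error_validation")
  expect_error(tangent_modulus(cv, window = 4),
    class = "arterymech_error_validation"
  )
})

test_that("strain stiffening yields nondecreasing tangent modulus", {
  # analytically convex curve, both methods
  cv <- data.frame(stretch = seq(1, 2, 0.05))
  cv$stress_kpa <- exp(3 * (cv$stretch - 1))
  for (m in c("window", "central")) {
    tm <- tangent_modulus(cv, method = m)
    expect_true(all(diff(tm$e_tan_kpa) > -1e-9))
  }
  # simulated noiseless curve in the strain-stiffening (pressurised) range
  truth <- cached_truth()
  sw <- simulate_pressure_sweep(truth, p_min = 30, step = 5, noise = FALSE) |>
    dplyr::mutate(test_type = "pressure_sweep", sample_id = "s1")
  circ <- build_stress_stretch(sw, default_unloaded_df(truth),
    axis = "circumferential"
  )
  tm <- tangent_modulus(circ)
  expect_true(all(diff(tm$e_tan_kpa) > -1e-9))
})

test_that("windowed tangent modulus tracks the analytic derivative", {
  truth <- cached_truth()
  rec <- sample_recording(truth, sweep_step = 2)
  circ <- build_stress_stretch(rec, default_unloaded_df(truth),
    axis = "circumferential"
  )
  tm <- tangent_modulus(circ, method = "window", window = 5)
  analytic <- wall_tangent_analytic(
    truth$params, circ$stretch, truth$ivs_true
  )$dsigma_theta_dlt_kpa
  n <- nrow(circ)
  interior <- 3:(n - 2)
  rel <- abs(tm$e_tan_kpa[interior] - analytic[interior]) /
    abs(analytic[interior])
  expect_lt(max(rel), 0.02)
})
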