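test_that("parameter sets are validated", {
  expect_error(artery_params(c_iso = -1), class = "arterymech_error_params")
  bad <- default_fibers()
  bad$c2[1] <- -0.5
  expect_error(artery_params(fibers = bad), class = "arterymech_error_params")
  asym <- default_fibers()
  asym$c1[3] <- 99 # breaks the +/- diagonal symmetry
  expect_error(artery_params(fibers = asym), class = "arterymech_error_params")
  zero <- default_fibers()
  zero$c1 <- 0
  expect_error(artery_params(c_iso = 0, fibers = zero),
    class = "arterymech_error_params"
  )
})

test_that("stiffening multiplies circumferential-plane stress everywhere", {
  ctrl <- artery_params("control")
  stiff2 <- stiffen_params(ctrl, 2)
  lt <- seq(1.05, 1.9, by = 0.05)
  s_c <- wall_stress_analytic(ctrl, lt, 1.8)$sigma_theta_kpa
  s_s <- wall_stress_analytic(stiff2, lt, 1.8)$sigma_theta_kpa
  expect_true(all(s_s > s_c))
})

test_that("calibrated presets hit their IVS setpoints", {
  expect_equal(cached_truth("control")$ivs_true, 1.85, tolerance = 0.002)
  expect_equal(cached_truth("stiff")$ivs_true, 1.79, tolerance = 0.002)
})

test_that("every emitted noiseless point satisfies membrane equilibrium", {
  truth <- cached_truth()
  sol <- solve_equilibrium(
    truth$params, truth$unloaded,
    pressure_mmhg = rep(seq(0, 140, 10), 3),
    lambda_z = rep(c(1.5, 1.85, 2.05), each = 15)
  )
  expect_true(all(sol$residual_rel < 1e-8))
})

test_that("force-length simulation follows the stretch protocol", {
  truth <- cached_truth()
  fl <- simulate_force_length_test(truth, noise = FALSE)
  expect_setequal(unique(fl$pressure_mmHg), c(90, 120, 140))
  # 10% increments of the unloaded length
  steps <- diff(sort(unique(fl$axial_stretch)))
  expect_equal(steps, rep(0.1, length(steps)))
  expect_error(simulate_force_length_test(truth, pressures = numeric(0)),
    class = "arterymech_error_validation"
  )
  expect_error(
    simulate_force_length_test(truth, stretch_grid = c(1.2, 1.1)),
    class = "arterymech_error_validation"
  )
})

test_that("noiseless curves cross near the spread-minimising oracle", {
  truth <- cached_truth()
  fl <- simulate_force_length_test(truth, noise = FALSE)
  oracle <- truth$ivs_true
  prs <- c(90, 120, 140)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      x <- pairwise_intersection(
        fl[fl$pressure_mmHg == prs[i], ],
        fl[fl$pressure_mmHg == prs[j], ]
      )
      expect_lt(abs(x - oracle), 0.02)
    }
  }
})

test_that("pressure sweep has inclusive grid and monotone diameter", {
  truth <- cached_truth()
  sw <- simulate_pressure_sweep(truth, noise = FALSE)
  expect_equal(nrow(sw), 15)
  expect_equal(sw$pressure_mmHg, seq(0, 140, 10))
  expect_true(all(diff(sw$outer_diameter_um) >= 0))
  expect_error(simulate_pressure_sweep(truth, axial_stretch = 0.9),
    class = "arterymech_error_validation"
  )
  expect_error(simulate_pressure_sweep(truth, step = 0),
    class = "arterymech_error_validation"
  )
})

test_that("noise honours the seed contract", {
  truth <- cached_truth()
  clean <- simulate_pressure_sweep(truth, noise = FALSE)
  n1 <- simulate_pressure_sweep(truth, seed = 1)
  n1b <- simulate_pressure_sweep(truth, seed = 1)
  n2 <- simulate_pressure_sweep(truth, seed = 2)
  expect_identical(n1, n1b)
  expect_false(identical(n1$force_mN, n2$force_mN))
  # noiseless columns (pressure, stretch) are shared across seeds
  expect_identical(n1$pressure_mmHg, n2$pressure_mmHg)
  expect_identical(n1$axial_stretch, n2$axial_stretch)
  expect_false(identical(n1$outer_diameter_um, clean$outer_diameter_um))
})

test_that("noiseless output is the expectation of noisy output", {
  truth <- cached_truth()
  clean <- simulate_pressure_sweep(truth,
    p_min = 0, p_max = 140, step = 70,
    noise = FALSE
  )
  reps <- 1000
  acc_od <- matrix(0, reps, 3)
  acc_f <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    s <- simulate_pressure_sweep(truth,
      p_min = 0, p_max = 140, step = 70,
      seed = 10000 + r
    )
    acc_od[r, ] <- s$outer_diameter_um
    acc_f[r, ] <- s$force_mN
  }
  se_od <- apply(acc_od, 2, sd) / sqrt(reps)
  se_f <- apply(acc_f, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(acc_od) - clean$outer_diameter_um) < 3 * se_od))
  expect_true(all(abs(colMeans(acc_f) - clean$force_mN) < 3 * se_f))
})

test_that("IVS oracle is deterministic, order-invariant and refinement-stable", {
  truth <- cached_truth()
  a <- simulator_oracle_ivs(truth, pressures = c(90, 120, 140))
  b <- simulator_oracle_ivs(truth, pressures = c(140, 90, 120))
  expect_identical(a, b)
  coarse <- simulator_oracle_ivs(truth, grid_step = 1e-3)
  expect_lt(abs(a - coarse), 1e-3 + 1e-9)
  full <- simulator_oracle_ivs(truth, grid_step = 1e-3, refine = FALSE)
  expect_equal(coarse, full, tolerance = 1e-9)
  expect_error(simulator_oracle_ivs(truth, pressures = 90),
    class = "arterymech_error_validation"
  )
  expect_error(simulator_oracle_ivs(truth, grid_step = 0.01),
    class = "arterymech_error_validation"
  )
})

test_that("equilibrium failure names the offending state", {
  # zero-stiffness wall except a tiny isotropic term cannot carry 500 mmHg
  weak <- artery_params(c_iso = 1e-6, fibers = tibble::tibble(
    family = "circumferential", c1 = 0, c2 = 0, alpha = 0
  ))
  err <- tryCatch(
    solve_equilibrium(weak, unloaded_geometry(), 500, 1.5),
    error = function(e) e
  )
  expect_s3_class(err, "arterymech_error_equilibrium")
  expect_match(conditionMessage(err), "500")
  expect_match(conditionMessage(err), "1.5")
})

test_that("cohort generation is reproducible and writes identical files", {
  cfg <- cohort_config(
    groups = tibble::tibble(group = c("a", "b"), n = c(2, 2)),
    seed = 99
  )
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings, c2$recordings)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
})

test_that("invalid cohort configs name the offending fields", {
  expect_error(
    cohort_config(groups = tibble::tibble(group = "a", n = 1)),
    regexp = "groups\\$n", class = "arterymech_error_config"
  )
  err <- tryCatch(
    cohort_config(
      groups = tibble::tibble(
        group = c("a", "b"), n = c(3, 3),
        multiplier = c(1, -2), ivs_target = c(NA, 0.5)
      ),
      noise_f_sd = -1
    ),
    error = function(e) e
  )
  expect_s3_class(err, "arterymech_error_config")
  expect_match(conditionMessage(err), "multiplier")
  expect_match(conditionMessage(err), "ivs_target")
  expect_match(conditionMessage(err), "noise_f_sd")
})

test_that("per-sample ground truths carry plausible jittered IVS values", {
  cohort <- small_cohort(n = 3, seed = 21)
  expect_true(all(cohort$truth$ivs_true > 1))
  # biological jitter moves each artery's IVS around its group setpoint but
  # keeps it inside the force-length protocol span
  expect_true(all(
    cohort$truth$ivs_true > min(cohort$config$stretch_grid) &
      cohort$truth$ivs_true < max(cohort$config$stretch_grid)
  ))
  expect_gt(stats::sd(cohort$truth$ivs_true), 0)
})
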