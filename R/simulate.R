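#' Ground-truth description of a simulated artery
#'
#' Bundles a constitutive parameter set, an unloaded geometry, the analytic
#' stress map, and the operational ground-truth in-vivo stretch (IVS).  The
#' ground-truth IVS is not a model parameter: it is defined operationally as
#' the axial stretch minimising the across-pressure spread of the noiseless
#' equilibrium transducer force (see [simulator_oracle_ivs()]), mirroring how
#' IVS is read off real force-length recordings.
#'
#' @param params An [artery_params()] object.
#' @param unloaded An [unloaded_geometry()] object.
#' @param pressures Pressures (mmHg) defining the force-length protocol used
#'   for the operational IVS.
#' @param grid_step Oracle grid step for the stored `ivs_true`.
#' @return Object of class `artery_ground_truth` with elements `params`,
#'   `unloaded`, `pressures`, `ivs_true`, and `stress_fn(lambda_theta,
#'   lambda_z)` returning the analytic stresses in kPa.
#' @examples
#' truth <- artery_ground_truth(artery_params("control"))
#' truth$ivs_true
#' @export
artery_ground_truth <- function(params,
                                unloaded = unloaded_geometry(),
                                pressures = c(90, 120, 140),
                                grid_step = 1e-4) {
  ivs <- oracle_ivs_params(params, unloaded, pressures, grid_step = grid_step)
  structure(
    list(
      params = params,
      unloaded = unloaded,
      pressures = pressures,
      ivs_true = ivs,
      stress_fn = function(lambda_theta, lambda_z) {
        wall_stress_analytic(params, lambda_theta, lambda_z)
      }
    ),
    class = "artery_ground_truth"
  )
}

#' @export
print.artery_ground_truth <- function(x, ...) {
  cat(
    "<artery_ground_truth> ivs_true =", format(x$ivs_true, digits = 5),
    "(pressures", paste(x$pressures, collapse = "/"), "mmHg)\n"
  )
  invisible(x)
}

#' Brute-force oracle for the ground-truth in-vivo stretch
#'
#' Scans a fine axial-stretch grid and returns the stretch minimising the
#' across-pressure relative spread `(max - min)/mean` of the noiseless
#' equilibrium transducer force.  Deterministic, and independent of the
#' curve-intersection pipeline estimator, so it serves as its oracle.
#'
#' With `refine = TRUE` (default) a coarse scan locates the minimum and the
#' fine grid is applied only in its neighbourhood; `refine = FALSE` performs
#' the full fine-grid scan (identical result for the unimodal spread profiles
#' this model produces, at much higher cost).
#'
#' @param truth An [artery_ground_truth()] object.
#' @param pressures Pressures in mmHg (>= 2 required).
#' @param grid_step Fine grid step in stretch units (<= 1e-3).
#' @param span Stretch interval scanned.
#' @param refine Use coarse-to-fine two-stage scan.
#' @return The minimising axial stretch (scalar).
#' @export
simulator_oracle_ivs <- function(truth, pressures = truth$pressures,
                                 grid_step = 1e-4, span = c(1.25, 2.35),
                                 refine = TRUE) {
  oracle_ivs_params(truth$params, truth$unloaded, pressures,
    grid_step = grid_step, span = span, refine = refine
  )
}

#' @rdname simulator_oracle_ivs
#' @param params,unloaded Parameter set and unloaded geometry (used
#'   internally before an `artery_ground_truth` exists).
#' @export
oracle_ivs_params <- function(params, unloaded, pressures,
                              grid_step = 1e-4, span = c(1.25, 2.35),
                              refine = TRUE) {
  if (length(pressures) < 2) {
    abort("IVS oracle needs >= 2 pressures", class = "arterymech_error_validation")
  }
  if (grid_step > 1e-3) {
    abort("grid_step must be <= 1e-3", class = "arterymech_error_validation")
  }
  scan <- function(grid) {
    np <- length(pressures)
    sol <- solve_equilibrium(params, unloaded,
      pressure_mmhg = rep(pressures, times = length(grid)),
      lambda_z = rep(grid, each = np)
    )
    fm <- matrix(sol$force_mN, nrow = np)
    mu <- colMeans(fm)
    spread <- (apply(fm, 2, max) - apply(fm, 2, min)) / mu
    spread[mu <= 0] <- Inf
    grid[which.min(spread)]
  }
  if (refine) {
    coarse_step <- max(grid_step, 5e-3)
    g0 <- scan(seq(span[1], span[2], by = coarse_step))
    if (coarse_step <= grid_step) {
      return(g0)
    }
    lo <- max(span[1], g0 - 2 * coarse_step)
    hi <- min(span[2], g0 + 2 * coarse_step)
    scan(seq(lo, hi, by = grid_step))
  } else {
    scan(seq(span[1], span[2], by = grid_step))
  }
}

#' Simulate a force-length test (axial stretch sweep at constant pressures)
#'
#' Emulates the myograph protocol in which the mounted vessel is axially
#' stretched in 10% increments at several constant lumen pressures while the
#' equilibrium transducer force (and outer diameter) is recorded.  Additive
#' Gaussian measurement noise (SDs from `truth$params`) is applied to the
#' recorded outer diameter and force; pressure and stretch are treated as
#' exactly controlled.
#'
#' @param truth An [artery_ground_truth()] object.
#' @param pressures Constant pressures (mmHg), one sweep per pressure.
#' @param stretch_grid Strictly increasing axial stretches, all > 1.  The
#'   default spans 1.4-2.1 in steps of 0.1 (10% of unloaded length).
#' @param noise Apply measurement noise?  `FALSE` returns the noiseless
#'   equilibrium values.
#' @param seed Seed for the noise draw; defaults to `truth$params$seed`.
#' @return Tidy tibble with columns `pressure_mmHg`, `axial_stretch`,
#'   `force_mN`, `outer_diameter_um` (one pressure sweep stacked per
#'   pressure).
#' @export
simulate_force_length_test <- function(truth,
                                       pressures = c(90, 120, 140),
                                       stretch_grid = seq(1.4, 2.1, by = 0.1),
                                       noise = TRUE,
                                       seed = truth$params$seed) {
  if (length(pressures) == 0 || any(pressures < 0)) {
    abort("pressures must be non-empty and non-negative",
      class = "arterymech_error_validation"
    )
  }
  if (any(diff(stretch_grid) <= 0) || any(stretch_grid <= 1)) {
    abort("stretch_grid must be strictly increasing with all values > 1",
      class = "arterymech_error_validation"
    )
  }
  sol <- solve_equilibrium(truth$params, truth$unloaded,
    pressure_mmhg = rep(pressures, each = length(stretch_grid)),
    lambda_z = rep(stretch_grid, times = length(pressures))
  )
  out <- sol[, c(
    "pressure_mmHg", "axial_stretch", "force_mN",
    "outer_diameter_um"
  )]
  add_measurement_noise(out, truth$params, noise, seed)
}

#' Simulate a pressure-outer diameter sweep at fixed axial stretch
#'
#' Emulates pressurisation of the vessel held at a fixed axial stretch
#' (normally its in-vivo stretch) in uniform pressure steps, recording outer
#' diameter and the transducer axial force at each step.
#'
#' @param truth An [artery_ground_truth()] object.
#' @param axial_stretch Fixed axial stretch (>= 1); defaults to
#'   `truth$ivs_true`.
#' @param p_min,p_max,step Pressure range and step (mmHg); the default
#'   0-140 by 10 gives 15 points inclusive of both ends.
#' @inheritParams simulate_force_length_test
#' @return Tidy tibble with columns `pressure_mmHg`, `axial_stretch`,
#'   `outer_diameter_um`, `force_mN`.
#' @export
simulate_pressure_sweep <- function(truth,
                                    axial_stretch = truth$ivs_true,
                                    p_min = 0, p_max = 140, step = 10,
                                    noise = TRUE,
                                    seed = truth$params$seed) {
  if (axial_stretch < 1) {
    abort("axial_stretch must be >= 1", class = "arterymech_error_validation")
  }
  if (step <= 0) {
    abort("step must be > 0", class = "arterymech_error_validation")
  }
  pressures <- seq(p_min, p_max, by = step)
  sol <- solve_equilibrium(truth$params, truth$unloaded,
    pressure_mmhg = pressures, lambda_z = axial_stretch
  )
  out <- sol[, c(
    "pressure_mmHg", "axial_stretch", "outer_diameter_um",
    "force_mN"
  )]
  add_measurement_noise(out, truth$params, noise, seed)
}

add_measurement_noise <- function(tbl, params, noise, seed) {
  if (!noise) {
    return(tbl)
  }
  draw <- function() {
    tbl$outer_diameter_um <- tbl$outer_diameter_um +
      rnorm(nrow(tbl), 0, params$noise_od_sd)
    tbl$force_mN <- tbl$force_mN + rnorm(nrow(tbl), 0, params$noise_f_sd)
    tbl
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Curve-level synthetic force-length curves with an exact common crossing
#'
#' Generates straight-line force-stretch curves that all pass exactly
#' through a designated point `(ivs, force_at_ivs)`, with slope increasing
#' in pressure so that higher-pressure curves lie below the lower-pressure
#' ones before the crossing and above after it.  This is the degenerate,
#' analytically known case used to validate the IVS estimator end to end.
#'
#' @param pressures Pressures (mmHg) labelling the curves.
#' @param ivs Designated common crossing stretch.
#' @param force_at_ivs Force at the crossing (mN).
#' @param slope_base Slope (mN per unit stretch) of the lowest-pressure curve.
#' @param slope_gain Fractional slope increase per 10 mmHg above the lowest
#'   pressure.
#' @param stretch_grid Sampled stretches.
#' @param noise_f_sd Additive Gaussian force noise SD (mN).
#' @param seed Noise seed.
#' @return Tidy tibble with `pressure_mmHg`, `axial_stretch`, `force_mN`.
#' @examples
#' synth_force_length_curves(ivs = 1.8)
#' @export
synth_force_length_curves <- function(pressures = c(90, 120, 140),
                                      ivs = 1.8, force_at_ivs = 5,
                                      slope_base = 20, slope_gain = 0.15,
                                      stretch_grid = seq(1.4, 2.1, by = 0.1),
                                      noise_f_sd = 0, seed = NULL) {
  p0 <- min(pressures)
  out <- purrr::map_dfr(pressures, function(p) {
    slope <- slope_base * (1 + slope_gain * (p - p0) / 10)
    tibble(
      pressure_mmHg = p,
      axial_stretch = stretch_grid,
      force_mN = force_at_ivs + slope * (stretch_grid - ivs)
    )
  })
  if (noise_f_sd > 0) {
    draw <- function() {
      out$force_mN <- out$force_mN + rnorm(nrow(out), 0, noise_f_sd)
      out
    }
    out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  out
}
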