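#' Solve membrane equilibrium of the simulated vessel
#'
#' For each requested (pressure, axial stretch) state, finds the mid-wall
#' circumferential stretch at which the Laplace equilibrium
#' `P = sigma_theta h / r_i` holds, with the loaded wall thickness obtained
#' from incompressibility: `r_m = lambda_theta R_m`,
#' `h = (R_o^2 - R_i^2) / (2 lambda_z r_m)`, `r_i = r_m - h/2`.
#'
#' The root of `g(lambda_theta) = sigma_theta h - P r_i` (which removes the
#' `1/r_i` singularity at the degenerate lower bound) is bracketed and then
#' refined by vectorized bisection to near machine precision; the residual of
#' every solution is checked against `tol` in relative pressure units.
#'
#' @param params An [artery_params()] object.
#' @param unloaded An [unloaded_geometry()] object.
#' @param pressure_mmhg Vector of lumen pressures (mmHg).
#' @param lambda_z Vector of axial stretches (recycled against pressure).
#' @param tol Maximum tolerated equilibrium residual, relative pressure units.
#' @return Tibble with one row per state: `pressure_mmHg`, `axial_stretch`,
#'   `lambda_theta`, `r_i_um`, `h_um`, `r_o_um`, `outer_diameter_um`,
#'   `sigma_theta_kpa`, `sigma_z_kpa`, `force_mN` (transducer force: total
#'   axial wall load minus the pressure-on-cap term), `residual_rel`.
#' @examples
#' solve_equilibrium(artery_params("control"), unloaded_geometry(),
#'   pressure_mmhg = 90, lambda_z = 1.85
#' )
#' @export
solve_equilibrium <- function(params, unloaded, pressure_mmhg, lambda_z,
                              tol = 1e-8) {
  n <- max(length(pressure_mmhg), length(lambda_z))
  P_mmhg <- rep_len(pressure_mmhg, n)
  lz <- rep_len(lambda_z, n)
  if (any(P_mmhg < 0)) {
    abort("pressures must be >= 0", class = "arterymech_error_validation")
  }
  if (any(lz <= 0)) {
    abort("axial stretch must be > 0", class = "arterymech_error_validation")
  }
  P <- P_mmhg * MMHG_TO_KPA

  A <- unloaded$A
  R_m <- unloaded$R_m

  gfun <- function(lt) {
    r_m <- lt * R_m
    h <- A / (2 * lz * r_m)
    r_i <- r_m - h / 2
    st <- stress_core(params, lt, lz)$st
    st * h - P * r_i
  }

  # lower bracket: just above the stretch where the lumen closes (r_i = 0)
  lo <- sqrt(A / (4 * lz * R_m^2)) * (1 + 1e-9)
  hi <- rep(4, n)
  glo <- gfun(lo)
  ghi <- gfun(hi)
  for (i in 1:3) { # expand upper bracket if needed
    open <- ghi < 0
    if (!any(open)) break
    hi[open] <- hi[open] * 2
    ghi <- gfun(hi)
  }
  bad <- glo > 0 | ghi < 0
  if (any(bad)) {
    j <- which(bad)[1]
    abort(
      sprintf(
        "equilibrium root not bracketed at P = %.6g mmHg, lambda_z = %.6g",
        P_mmhg[j], lz[j]
      ),
      class = "arterymech_error_equilibrium"
    )
  }
  for (i in 1:90) {
    mid <- (lo + hi) / 2
    gm <- gfun(mid)
    up <- gm <= 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  lt <- (lo + hi) / 2

  r_m <- lt * R_m
  h <- A / (2 * lz * r_m)
  r_i <- r_m - h / 2
  r_o <- r_m + h / 2
  s <- stress_core(params, lt, lz)
  # kPa * um^2 -> mN carries a factor 1e-6
  force <- (s$sz * pi * h * (2 * r_i + h) - P * pi * r_i^2) * 1e-6
  residual <- abs(s$st * h / r_i - P) / pmax(abs(P), 1)
  if (any(residual > tol)) {
    abort("equilibrium residual exceeded tolerance",
      class = "arterymech_error_equilibrium"
    )
  }
  tibble(
    pressure_mmHg = P_mmhg,
    axial_stretch = lz,
    lambda_theta = lt,
    r_i_um = r_i,
    h_um = h,
    r_o_um = r_o,
    outer_diameter_um = 2 * r_o,
    sigma_theta_kpa = s$st,
    sigma_z_kpa = s$sz,
    force_mN = force,
    residual_rel = residual
  )
}
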