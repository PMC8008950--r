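#' Analytic biaxial Cauchy stresses of the four-fiber-family wall model
#'
#' Thin-wall, incompressible strain-energy model: a neo-Hookean isotropic
#' matrix plus exponential fiber families,
#' `W = c_iso/2 (I1 - 3) + sum_k c1_k/(4 c2_k) (exp(c2_k (lam_k^2 - 1)^2) - 1)`
#' with `lam_k^2 = lambda_theta^2 cos^2(alpha_k) + lambda_z^2 sin^2(alpha_k)`
#' and radial stretch `1/(lambda_theta lambda_z)` from incompressibility.
#' Under the membrane assumption (radial stress negligible) the mean Cauchy
#' stresses are `sigma_theta = lambda_theta dW/dlambda_theta` and
#' `sigma_z = lambda_z dW/dlambda_z`, evaluated here in closed form:
#'
#' `sigma_theta = c_iso (lt^2 - lr^2) +
#'    sum_k c1_k lt^2 cos^2(a_k) (lam_k^2 - 1) exp(c2_k (lam_k^2 - 1)^2)`
#'
#' and symmetrically for `sigma_z` with `sin^2(a_k)` and `lz^2`.
#'
#' @param params An [artery_params()] object.
#' @param lambda_theta,lambda_z Stretch vectors (recycled to common length).
#' @return Tibble with columns `lambda_theta`, `lambda_z`, `sigma_theta_kpa`,
#'   `sigma_z_kpa`.
#' @examples
#' wall_stress_analytic(artery_params("control"), 1.5, 1.85)
#' @export
wall_stress_analytic <- function(params, lambda_theta, lambda_z) {
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n)
  lz <- rep_len(lambda_z, n)
  if (any(lt <= 0) || any(lz <= 0)) {
    abort("stretches must be > 0", class = "arterymech_error_params")
  }
  s <- stress_core(params, lt, lz)
  tibble(
    lambda_theta = lt, lambda_z = lz,
    sigma_theta_kpa = s$st, sigma_z_kpa = s$sz
  )
}

# allocation-light kernel shared with the equilibrium bisection
stress_core <- function(params, lt, lz) {
  lr2 <- 1 / (lt^2 * lz^2)
  st <- params$c_iso * (lt^2 - lr2)
  sz <- params$c_iso * (lz^2 - lr2)
  c1 <- params$fibers$c1
  c2 <- params$fibers$c2
  alpha <- params$fibers$alpha
  for (k in seq_along(c1)) {
    c2a <- cos(alpha[k])^2
    s2a <- sin(alpha[k])^2
    lk2 <- lt^2 * c2a + lz^2 * s2a
    common <- c1[k] * (lk2 - 1) * exp(c2[k] * (lk2 - 1)^2)
    st <- st + common * lt^2 * c2a
    sz <- sz + common * lz^2 * s2a
  }
  list(st = st, sz = sz)
}

#' Analytic tangent moduli of the wall model
#'
#' Partial derivatives `d sigma_theta / d lambda_theta` (at fixed axial
#' stretch) and `d sigma_z / d lambda_z` (at fixed circumferential stretch)
#' of [wall_stress_analytic()], in closed form.  Used as the independent
#' reference when validating numerically differentiated tangent-modulus
#' curves.
#'
#' @inheritParams wall_stress_analytic
#' @return Tibble with columns `lambda_theta`, `lambda_z`,
#'   `dsigma_theta_dlt_kpa`, `dsigma_z_dlz_kpa`.
#' @export
wall_tangent_analytic <- function(params, lambda_theta, lambda_z) {
  n <- max(length(lambda_theta), length(lambda_z))
  lt <- rep_len(lambda_theta, n)
  lz <- rep_len(lambda_z, n)
  # d/dlt [c (lt^2 - 1/(lt^2 lz^2))] = c (2 lt + 2/(lt^3 lz^2))
  dst <- params$c_iso * (2 * lt + 2 / (lt^3 * lz^2))
  dsz <- params$c_iso * (2 * lz + 2 / (lz^3 * lt^2))
  f <- params$fibers
  for (k in seq_len(nrow(f))) {
    c2a <- cos(f$alpha[k])^2
    s2a <- sin(f$alpha[k])^2
    lk2 <- lt^2 * c2a + lz^2 * s2a
    e <- exp(f$c2[k] * (lk2 - 1)^2)
    # sigma_theta_k = c1 lt^2 c2a (lk2-1) e ; dlk2/dlt = 2 lt c2a
    dst <- dst + f$c1[k] * c2a * e * (
      2 * lt * (lk2 - 1) +
        lt^2 * (2 * lt * c2a) * (1 + 2 * f$c2[k] * (lk2 - 1)^2)
    )
    dsz <- dsz + f$c1[k] * s2a * e * (
      2 * lz * (lk2 - 1) +
        lz^2 * (2 * lz * s2a) * (1 + 2 * f$c2[k] * (lk2 - 1)^2)
    )
  }
  tibble(
    lambda_theta = lt, lambda_z = lz,
    dsigma_theta_dlt_kpa = dst, dsigma_z_dlz_kpa = dsz
  )
}
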