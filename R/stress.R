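#' Mean circumferential (hoop) Cauchy wall stress
#'
#' Laplace mean-wall stress `sigma_theta = P r_i / h`, with the lumen
#' pressure converted at 1 mmHg = 0.133322 kPa.  Radii and thickness may be
#' in any common length unit (the ratio is dimensionless); stresses are
#' returned in kPa.
#'
#' @param pressure_mmhg Lumen pressure (mmHg), vectorized.
#' @param r_i_um Loaded inner radius.
#' @param h_um Loaded wall thickness (same unit as `r_i_um`).
#' @return Circumferential Cauchy stress (kPa).
#' @examples
#' circumferential_stress(100, r_i_um = 188.76, h_um = 21.24)
#' @export
circumferential_stress <- function(pressure_mmhg, r_i_um, h_um) {
  if (any(h_um <= 0) || any(r_i_um <= 0)) {
    abort("degenerate geometry: need r_i > 0 and h > 0",
      class = "arterymech_error_geometry"
    )
  }
  pressure_mmhg * MMHG_TO_KPA * r_i_um / h_um
}

#' Mean axial Cauchy wall stress
#'
#' Force balance on a capped tube: the wall cross-section
#' `pi h (2 r_i + h)` carries the transducer force plus the pressure thrust
#' on the cap, `sigma_z = (f + P pi r_i^2) / (pi h (2 r_i + h))`.  Geometry
#' is taken in micrometres and force in millinewtons; the returned stress is
#' in kPa.
#'
#' @param force_mn Transducer axial force (mN), vectorized.
#' @param pressure_mmhg Lumen pressure (mmHg).
#' @param r_i_um Loaded inner radius (um by default).
#' @param h_um Loaded wall thickness (same unit as `r_i_um`).
#' @param unit Length unit of the geometry arguments (`"um"` or `"mm"`);
#'   inputs are normalised internally so the stress value is
#'   unit-independent.
#' @return Axial Cauchy stress (kPa).
#' @examples
#' axial_stress(2.0, 100, r_i_um = 188.76, h_um = 21.24)
#' @export
axial_stress <- function(force_mn, pressure_mmhg, r_i_um, h_um,
                         unit = c("um", "mm")) {
  unit <- match.arg(unit)
  if (unit == "mm") {
    r_i_um <- r_i_um * 1000
    h_um <- h_um * 1000
  }
  if (any(h_um <= 0) || any(r_i_um <= 0)) {
    abort("degenerate geometry: need r_i > 0 and h > 0",
      class = "arterymech_error_geometry"
    )
  }
  p_kpa <- pressure_mmhg * MMHG_TO_KPA
  # mN / um^2 = 1e6 kPa
  (force_mn * 1e6 + p_kpa * pi * r_i_um^2) / (pi * h_um * (2 * r_i_um + h_um))
}

#' Append biaxial Cauchy stresses to a loaded-geometry table
#'
#' Convenience wrapper: given rows that already carry `pressure_mmHg`,
#' `r_i_um`, `h_um` (from [loaded_geometry()]) and, for the axial stress,
#' `force_mN`, appends `sigma_theta_kpa` and (when force is present)
#' `sigma_z_kpa`.
#'
#' @param data Data frame with the columns named above.
#' @return The input tibble with stress columns appended.
#' @export
wall_stress <- function(data) {
  need <- c("pressure_mmHg", "r_i_um", "h_um")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  out <- as_tibble(data)
  out$sigma_theta_kpa <- circumferential_stress(
    out$pressure_mmHg, out$r_i_um, out$h_um
  )
  if ("force_mN" %in% names(out)) {
    out$sigma_z_kpa <- axial_stress(
      out$force_mN, out$pressure_mmHg, out$r_i_um, out$h_um
    )
  }
  out
}

#' Build a stress-stretch curve for one sample
#'
#' Constructs the tidy stress-stretch curve for one axis from a sample's
#' recordings:
#'
#' * `axis = "circumferential"`: one point per pressure step of the
#'   pressure-outer-diameter sweep performed at the sample's in-vivo stretch;
#'   x is the circumferential stretch, y the hoop stress `P r_i / h`.
#' * `axis = "axial"`: one point per stretch step of the force-length test at
#'   the stated constant context pressure (90 mmHg by default; 80 mmHg is
#'   the convention for very young animals); x is the axial stretch, y the
#'   axial stress.
#'
#' @param recording Tidy recording rows for one sample (columns `test_type`,
#'   `pressure_mmHg`, `axial_stretch`, `outer_diameter_um`, `force_mN`).
#' @param unloaded [unloaded_geometry()] for the sample.
#' @param axis `"circumferential"` or `"axial"`.
#' @param context_pressure Constant pressure (mmHg) selecting the axial
#'   force-length sweep; ignored for the circumferential axis.
#' @param stretch_ref Passed to [loaded_geometry()].
#' @param sample_id Optional label carried through to the output.
#' @return Tibble with columns `sample_id`, `axis`, `stretch`, `stress_kpa`,
#'   `context_pressure_mmHg`, ordered by increasing stretch.
#' @export
build_stress_stretch <- function(recording, unloaded,
                                 axis = c("circumferential", "axial"),
                                 context_pressure = 90,
                                 stretch_ref = c("midwall", "inner"),
                                 sample_id = NA_character_) {
  axis <- match.arg(axis)
  stretch_ref <- match.arg(stretch_ref)
  unloaded <- as_unloaded_geometry(unloaded)
  if (axis == "circumferential") {
    rows <- recording[recording$test_type == "pressure_sweep", ]
    if (nrow(rows) == 0) {
      abort("no pressure_sweep rows in recording",
        class = "arterymech_error_validation"
      )
    }
    geo <- loaded_geometry(rows, unloaded,
      stretch_ref = stretch_ref,
      sample_id = sample_id
    )
    out <- tibble(
      sample_id = sample_id,
      axis = axis,
      stretch = geo$lambda_theta,
      stress_kpa = circumferential_stress(
        geo$pressure_mmHg, geo$r_i_um, geo$h_um
      ),
      pressure_mmHg = geo$pressure_mmHg,
      context_pressure_mmHg = NA_real_
    )
  } else {
    rows <- recording[recording$test_type == "force_length" &
      abs(recording$pressure_mmHg - context_pressure) < 1e-9, ]
    if (nrow(rows) == 0) {
      abort(
        sprintf(
          "no force_length rows at context pressure %g mmHg",
          context_pressure
        ),
        class = "arterymech_error_validation"
      )
    }
    geo <- loaded_geometry(rows, unloaded,
      stretch_ref = stretch_ref,
      sample_id = sample_id
    )
    out <- tibble(
      sample_id = sample_id,
      axis = axis,
      stretch = geo$axial_stretch,
      stress_kpa = axial_stress(
        geo$force_mN, geo$pressure_mmHg, geo$r_i_um, geo$h_um
      ),
      pressure_mmHg = geo$pressure_mmHg,
      context_pressure_mmHg = context_pressure
    )
  }
  out[order(out$stretch), ]
}
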