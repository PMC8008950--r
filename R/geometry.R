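#' Unloaded (unstretched, unpressurized) vessel geometry
#'
#' Reference dimensions of the excised vessel, measured on the myograph
#' before loading: outer diameter and wall thickness, from which the
#' unloaded inner radius follows.  All lengths in micrometres.
#'
#' @param od_um Unloaded outer diameter (um).
#' @param h_um Unloaded wall thickness (um); must satisfy `0 < h < od/2`.
#' @return An object of class `unloaded_geometry` with elements `R_o`, `H`,
#'   `R_i`, the mid-wall radius `R_m`, and the wall "area term"
#'   `A = R_o^2 - R_i^2` (um^2) used by incompressibility.
#' @examples
#' unloaded_geometry(od_um = 400, h_um = 60)
#' @export
unloaded_geometry <- function(od_um = 400, h_um = 60) {
  if (!is.finite(od_um) || !is.finite(h_um) || h_um <= 0 || h_um >= od_um / 2) {
    abort("need 0 < h_um < od_um / 2", class = "arterymech_error_geometry")
  }
  R_o <- od_um / 2
  R_i <- R_o - h_um
  structure(
    list(
      R_o = R_o, H = h_um, R_i = R_i,
      R_m = (R_i + R_o) / 2,
      A = R_o^2 - R_i^2
    ),
    class = "unloaded_geometry"
  )
}

#' @export
print.unloaded_geometry <- function(x, ...) {
  cat(
    "<unloaded_geometry> OD", 2 * x$R_o, "um, wall", x$H,
    "um (R_i", x$R_i, "um)\n"
  )
  invisible(x)
}

#' Loaded geometry and biaxial stretches from measured outer diameter
#'
#' Converts outer diameters measured during a pressure sweep (or any loaded
#' state) into loaded inner radius, wall thickness, and circumferential
#' stretch, assuming wall incompressibility: the wall cross-sectional area
#' times the axial stretch is conserved,
#' `pi (r_o^2 - r_i^2) lambda_z = pi (R_o^2 - R_i^2)`, so
#' `r_i = sqrt(r_o^2 - (R_o^2 - R_i^2) / lambda_z)`.
#'
#' Circumferential stretch defaults to the mid-wall convention
#' `lambda_theta = (r_i + h/2) / (R_i + H/2)`; the inner-wall alternative
#' `r_i / R_i` is available via `stretch_ref = "inner"`.
#'
#' @param data Data frame with at least the columns `outer_diameter_um` and
#'   `axial_stretch` (one row per measured state).
#' @param unloaded An [unloaded_geometry()] object (or a one-row data frame
#'   with columns `unloaded_od_um`, `unloaded_h_um`).
#' @param stretch_ref `"midwall"` (default) or `"inner"` reference radius for
#'   the circumferential stretch.
#' @param sample_id Optional label used in error messages.
#' @return The input tibble with columns `r_o_um`, `r_i_um`, `h_um`, and
#'   `lambda_theta` appended.
#' @examples
#' g <- unloaded_geometry(400, 80)
#' d <- data.frame(outer_diameter_um = 420, axial_stretch = 1.7)
#' loaded_geometry(d, g)
#' @export
loaded_geometry <- function(data, unloaded, stretch_ref = c("midwall", "inner"),
                            sample_id = NULL) {
  stretch_ref <- match.arg(stretch_ref)
  unloaded <- as_unloaded_geometry(unloaded)
  need <- c("outer_diameter_um", "axial_stretch")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  od <- data$outer_diameter_um
  lz <- data$axial_stretch
  if (any(lz <= 0)) {
    abort("axial_stretch must be > 0", class = "arterymech_error_validation")
  }
  r_o <- od / 2
  disc <- r_o^2 - unloaded$A / lz
  bad <- which(!(disc > 0))
  if (length(bad)) {
    abort(
      paste0(
        "degenerate geometry (wall would exceed lumen)",
        if (!is.null(sample_id)) paste0(" for sample ", sample_id),
        " at row(s) ", paste(bad, collapse = ", "),
        ": outer diameter below incompressibility bound ",
        "2*sqrt((R_o^2 - R_i^2)/lambda_z)"
      ),
      class = "arterymech_error_geometry"
    )
  }
  r_i <- sqrt(disc)
  h <- r_o - r_i
  lt <- switch(stretch_ref,
    midwall = (r_i + h / 2) / (unloaded$R_i + unloaded$H / 2),
    inner = r_i / unloaded$R_i
  )
  out <- as_tibble(data)
  out$r_o_um <- r_o
  out$r_i_um <- r_i
  out$h_um <- h
  out$lambda_theta <- lt
  out
}

#' Coerce a one-row geometry record to an `unloaded_geometry`
#' @keywords internal
as_unloaded_geometry <- function(x) {
  if (inherits(x, "unloaded_geometry")) {
    return(x)
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1 ||
      !all(c("unloaded_od_um", "unloaded_h_um") %in% names(x))) {
      abort(
        "geometry record must be one row with unloaded_od_um, unloaded_h_um",
        class = "arterymech_error_validation"
      )
    }
    return(unloaded_geometry(x$unloaded_od_um, x$unloaded_h_um))
  }
  abort("cannot interpret unloaded geometry", class = "arterymech_error_validation")
}
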