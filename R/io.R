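#' Read and validate a recordings table
#'
#' Reads the tidy recording CSV (RFC-4180, UTF-8, '.' decimal) produced by
#' the instrument-export or the simulator.  Required columns (units embedded
#' in the names to prevent silent unit mistakes): `sample_id`, `test_type`
#' (`force_length` or `pressure_sweep`), `pressure_mmHg`, `axial_stretch`,
#' `outer_diameter_um`, `force_mN`.  Unknown extra columns are preserved
#' with a warning.  Validation failures report the offending row numbers.
#'
#' @param path CSV file path.
#' @return Validated tibble of recordings.
#' @export
read_recordings <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_recordings(tbl, source = path)
}

#' @rdname read_recordings
#' @param data In-memory data frame to validate instead of a file.
#' @param source Label used in messages.
#' @export
validate_recordings <- function(data, source = "recordings") {
  need <- c(
    "sample_id", "test_type", "pressure_mmHg", "axial_stretch",
    "outer_diameter_um", "force_mN"
  )
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(
      paste0(source, ": missing columns: ", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  extra <- setdiff(names(data), need)
  if (length(extra)) {
    warn(paste0(
      source, ": unrecognized columns preserved: ",
      paste(extra, collapse = ", ")
    ))
  }
  bad_type <- which(!data$test_type %in% c("force_length", "pressure_sweep"))
  if (length(bad_type)) {
    abort(
      paste0(
        source, ": invalid test_type at row(s) ",
        paste(head(bad_type, 5), collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  bad_p <- which(!is.finite(data$pressure_mmHg) | data$pressure_mmHg < 0)
  if (length(bad_p)) {
    abort(
      paste0(
        source, ": negative or non-finite pressure at row(s) ",
        paste(head(bad_p, 5), collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  bad_s <- which(!is.finite(data$axial_stretch) | data$axial_stretch <= 0)
  if (length(bad_s)) {
    abort(
      paste0(
        source, ": non-positive axial stretch at row(s) ",
        paste(head(bad_s, 5), collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  key <- paste(data$sample_id, data$test_type, data$pressure_mmHg,
    data$axial_stretch,
    sep = "\r"
  )
  dup <- which(duplicated(key))
  if (length(dup)) {
    abort(
      paste0(
        source, ": duplicate (sample, test, pressure, stretch) keys at row(s) ",
        paste(head(dup, 5), collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  as_tibble(data)
}

#' Read the per-sample unloaded geometry table
#'
#' Columns: `sample_id`, `unloaded_od_um`, `unloaded_h_um`, and optionally
#' `n_sections_averaged` (the unloaded dimensions are averages over several
#' wall sections).
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_geometry <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "unloaded_od_um", "unloaded_h_um")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0(
      path, ": missing columns: ",
      paste(miss, collapse = ", ")
    ), class = "arterymech_error_validation")
  }
  bad <- which(!is.finite(tbl$unloaded_od_um) | !is.finite(tbl$unloaded_h_um) |
    tbl$unloaded_h_um <= 0 |
    tbl$unloaded_h_um >= tbl$unloaded_od_um / 2)
  if (length(bad)) {
    abort(
      paste0(
        path, ": invalid unloaded geometry at row(s) ",
        paste(head(bad, 5), collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  if (anyDuplicated(tbl$sample_id)) {
    abort(paste0(path, ": duplicate sample_id"),
      class = "arterymech_error_validation"
    )
  }
  tbl
}

#' Read the per-sample metadata table
#'
#' Columns: `sample_id`, `group`, and optionally `sex`, `age_label`.
#'
#' @param path CSV file path.
#' @return Validated tibble.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0(
      path, ": missing columns: ",
      paste(miss, collapse = ", ")
    ), class = "arterymech_error_validation")
  }
  tbl
}

#' Analysis configuration
#'
#' Tunable settings of the analysis pipeline, with defaults matching the
#' standard myograph protocol: force-length tests at 90/120/140 mmHg, a
#' 0-140 mmHg sweep in 10 mmHg steps, the axial stress-stretch curve taken
#' at a 90 mmHg context pressure, and the 25% axial-force QC exclusion rule.
#'
#' @param pressures Force-length protocol pressures (mmHg).
#' @param sweep Pressure sweep `c(min, max, step)` (mmHg).
#' @param axial_context_pressure Constant pressure (mmHg) of the axial
#'   stress-stretch curve (90 by default; 80 for very young animals).
#' @param qc_threshold Maximum tolerated relative axial-force spread.
#' @param qc_pressure_floor Pressure floor (mmHg) of the QC statistic.
#' @param dispersion `"se"` or `"sd"` for group curve summaries.
#' @param stretch_ref Circumferential stretch convention
#'   (`"midwall"`/`"inner"`).
#' @param tangent_method,tangent_window Tangent-modulus settings
#'   (see [tangent_modulus()]).
#' @param reference_group Group label used as the comparison reference;
#'   `NULL` takes the first group encountered.
#' @param seed Seed recorded in the manifest.
#' @return Validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(pressures = c(90, 120, 140),
                            sweep = c(0, 140, 10),
                            axial_context_pressure = 90,
                            qc_threshold = 0.25,
                            qc_pressure_floor = 20,
                            dispersion = c("se", "sd"),
                            stretch_ref = c("midwall", "inner"),
                            tangent_method = c("window", "central"),
                            tangent_window = 5,
                            reference_group = NULL,
                            seed = 1L) {
  cfg <- structure(
    list(
      pressures = pressures, sweep = sweep,
      axial_context_pressure = axial_context_pressure,
      qc_threshold = qc_threshold, qc_pressure_floor = qc_pressure_floor,
      dispersion = match.arg(dispersion),
      stretch_ref = match.arg(stretch_ref),
      tangent_method = match.arg(tangent_method),
      tangent_window = tangent_window,
      reference_group = reference_group,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
  bad <- character(0)
  if (length(cfg$pressures) < 2 || any(cfg$pressures < 0)) bad <- c(bad, "pressures")
  if (length(cfg$sweep) != 3 || cfg$sweep[3] <= 0) bad <- c(bad, "sweep")
  if (cfg$axial_context_pressure < 0) bad <- c(bad, "axial_context_pressure")
  if (cfg$qc_threshold <= 0) bad <- c(bad, "qc_threshold")
  if (cfg$qc_pressure_floor < 0) bad <- c(bad, "qc_pressure_floor")
  if (cfg$tangent_window < 3 || cfg$tangent_window %% 2 == 0) {
    bad <- c(bad, "tangent_window")
  }
  if (length(bad)) {
    abort(paste0(
      "invalid pipeline config field(s): ",
      paste(bad, collapse = "; ")
    ), class = "arterymech_error_config")
  }
  cfg
}

#' Write / read a pipeline configuration as JSON
#' @param config A [pipeline_config()] object.
#' @param path JSON file path.
#' @return `read_config` returns a `pipeline_config`; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty <- vapply(
    raw, function(v) is.null(v) || (is.list(v) && !length(v)), logical(1)
  )
  do.call(pipeline_config, raw[!empty])
}
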