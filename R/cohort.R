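#' Specify a simulated cohort
#'
#' Describes the groups of a simulated inflation-extension study.  Each
#' group starts from a preset parameter set, optionally scaled by a
#' circumferential-plane fiber-stiffness multiplier ([stiffen_params()]) and
#' optionally recalibrated so its ground-truth IVS hits a target
#' ([calibrate_ivs()]).  Per-animal biological variability is emulated by
#' log-normal jitter of the stiffness coefficients and of the unloaded
#' geometry.
#'
#' @param groups Data frame with one row per group and columns `group`
#'   (label), `n` (animals, >= 2), and optionally `preset`
#'   (`"control"`/`"stiff"`, default control), `multiplier` (fiber-stiffness
#'   scale, default 1), `ivs_target` (`NA` to keep the preset's IVS).
#' @param pressures Force-length protocol pressures (mmHg).
#' @param stretch_grid Force-length stretch grid.
#' @param sweep Pressure sweep `c(min, max, step)` in mmHg.
#' @param unloaded_od_um,unloaded_h_um Mean unloaded geometry (um).
#' @param geometry_cv Coefficient of variation of the per-animal unloaded
#'   geometry jitter (log-normal).
#' @param param_sd_log Log-scale SD of the per-animal stiffness jitter
#'   (see [jitter_params()]).
#' @param noise_od_sd,noise_f_sd Measurement noise SDs (um, mN).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return Validated object of class `cohort_config`.
#' @examples
#' cohort_config(seed = 1)
#' @export
cohort_config <- function(groups = tibble(
                            group = c("control", "stiff"),
                            n = c(7, 7),
                            preset = c("control", "stiff"),
                            multiplier = c(1, 1),
                            ivs_target = c(NA_real_, NA_real_)
                          ),
                          pressures = c(90, 120, 140),
                          stretch_grid = seq(1.4, 2.1, by = 0.1),
                          sweep = c(0, 140, 10),
                          unloaded_od_um = 400,
                          unloaded_h_um = 60,
                          geometry_cv = 0.04,
                          param_sd_log = 0.12,
                          noise_od_sd = 2,
                          noise_f_sd = 0.05,
                          seed = 1L) {
  groups <- as_tibble(groups)
  if (!all(c("group", "n") %in% names(groups))) {
    abort("groups needs columns: group, n", class = "arterymech_error_config")
  }
  if (!("preset" %in% names(groups))) groups$preset <- "control"
  if (!("multiplier" %in% names(groups))) groups$multiplier <- 1
  if (!("ivs_target" %in% names(groups))) groups$ivs_target <- NA_real_
  cfg <- structure(
    list(
      groups = groups, pressures = pressures, stretch_grid = stretch_grid,
      sweep = sweep, unloaded_od_um = unloaded_od_um,
      unloaded_h_um = unloaded_h_um, geometry_cv = geometry_cv,
      param_sd_log = param_sd_log, noise_od_sd = noise_od_sd,
      noise_f_sd = noise_f_sd, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  g <- cfg$groups
  if (any(g$n < 2)) bad <- c(bad, "groups$n (need n >= 2 per group)")
  if (anyDuplicated(g$group)) bad <- c(bad, "groups$group (duplicate labels)")
  if (!all(g$preset %in% c("control", "stiff"))) bad <- c(bad, "groups$preset")
  if (any(g$multiplier <= 0)) bad <- c(bad, "groups$multiplier (must be > 0)")
  if (any(!is.na(g$ivs_target) & g$ivs_target <= 1)) {
    bad <- c(bad, "groups$ivs_target (must be > 1)")
  }
  if (length(cfg$pressures) < 2 || any(cfg$pressures < 0)) {
    bad <- c(bad, "pressures (need >= 2, non-negative)")
  }
  if (any(diff(cfg$stretch_grid) <= 0) || any(cfg$stretch_grid <= 1)) {
    bad <- c(bad, "stretch_grid (strictly increasing, > 1)")
  }
  if (length(cfg$sweep) != 3 || cfg$sweep[3] <= 0 ||
    cfg$sweep[2] <= cfg$sweep[1] || cfg$sweep[1] < 0) {
    bad <- c(bad, "sweep (need c(min, max, step), step > 0)")
  }
  for (nm in c(
    "unloaded_od_um", "unloaded_h_um", "geometry_cv", "param_sd_log",
    "noise_od_sd", "noise_f_sd"
  )) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      bad <- c(bad, nm)
    }
  }
  if (length(bad)) {
    abort(
      paste0(
        "invalid cohort config field(s): ",
        paste(bad, collapse = "; ")
      ),
      class = "arterymech_error_config"
    )
  }
  cfg
}

#' Simulate a full cohort of inflation-extension experiments
#'
#' Draws per-animal parameter sets and unloaded geometries for each group of
#' `config`, computes each sample's operational ground-truth IVS, and
#' simulates the complete myograph protocol per sample: a force-length test
#' at the protocol pressures and a pressure sweep at the sample's true IVS,
#' both with measurement noise.
#'
#' Entirely deterministic given `config$seed`: re-running with the same
#' config reproduces the same dataset bundle.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `cohort_bundle`:
#' \describe{
#'   \item{recordings}{tidy recording table (sample_id, test_type,
#'     pressure_mmHg, axial_stretch, outer_diameter_um, force_mN)}
#'   \item{geometry}{per-sample unloaded geometry}
#'   \item{metadata}{per-sample group, sex, age label}
#'   \item{truth}{per-sample ground truth (group, ivs_true, parameters)}
#' }
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' }
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  group_params <- lapply(seq_len(nrow(config$groups)), function(i) {
    g <- config$groups[i, ]
    p <- artery_params(g$preset,
      noise_od_sd = config$noise_od_sd,
      noise_f_sd = config$noise_f_sd
    )
    if (g$multiplier != 1) p <- stiffen_params(p, g$multiplier)
    if (!is.na(g$ivs_target)) {
      p <- calibrate_ivs(p, g$ivs_target,
        unloaded = unloaded_geometry(config$unloaded_od_um, config$unloaded_h_um),
        pressures = config$pressures
      )
    }
    p
  })
  withr::with_seed(config$seed, {
    samples <- purrr::map_dfr(seq_len(nrow(config$groups)), function(i) {
      g <- config$groups[i, ]
      purrr::map_dfr(seq_len(g$n), function(j) {
        tibble(
          sample_id = sprintf("%s_%02d", g$group, j),
          group = g$group,
          sex = if (j %% 2 == 1) "M" else "F",
          age_label = "2mo",
          group_idx = i
        )
      })
    })
    out <- purrr::map(seq_len(nrow(samples)), function(k) {
      s <- samples[k, ]
      p <- jitter_params(group_params[[s$group_idx]], config$param_sd_log)
      od <- config$unloaded_od_um * exp(rnorm(1, 0, config$geometry_cv))
      h <- config$unloaded_h_um * exp(rnorm(1, 0, config$geometry_cv))
      un <- unloaded_geometry(od, h)
      truth <- artery_ground_truth(p, un, pressures = config$pressures)
      noise_seed <- sample.int(1e8, 1)
      fl <- simulate_force_length_test(truth,
        pressures = config$pressures,
        stretch_grid = config$stretch_grid, seed = noise_seed
      )
      sw <- simulate_pressure_sweep(truth,
        axial_stretch = truth$ivs_true,
        p_min = config$sweep[1], p_max = config$sweep[2],
        step = config$sweep[3], seed = noise_seed + 1L
      )
      rec <- dplyr::bind_rows(
        dplyr::mutate(fl, test_type = "force_length"),
        dplyr::mutate(sw, test_type = "pressure_sweep")
      )
      rec$sample_id <- s$sample_id
      list(
        recordings = rec[, c(
          "sample_id", "test_type", "pressure_mmHg",
          "axial_stretch", "outer_diameter_um", "force_mN"
        )],
        geometry = tibble(
          sample_id = s$sample_id, unloaded_od_um = od,
          unloaded_h_um = h, n_sections_averaged = 3L
        ),
        truth = tibble(
          sample_id = s$sample_id, group = s$group,
          ivs_true = truth$ivs_true,
          params = list(p)
        )
      )
    })
    structure(
      list(
        recordings = purrr::map_dfr(out, "recordings"),
        geometry = purrr::map_dfr(out, "geometry"),
        metadata = samples[, c("sample_id", "group", "sex", "age_label")],
        truth = purrr::map_dfr(out, "truth"),
        config = config
      ),
      class = "cohort_bundle"
    )
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(
    "<cohort_bundle>", nrow(x$metadata), "samples in",
    nrow(x$config$groups), "groups;",
    nrow(x$recordings), "recording rows\n"
  )
  invisible(x)
}

#' Write a simulated cohort to disk in the package CSV format
#'
#' Writes `recordings.csv`, `geometry.csv`, `metadata.csv`, and a
#' `truth/<sample_id>.json` ground-truth sidecar per sample (constitutive
#' parameters and true IVS).  Output is byte-identical across reruns of the
#' same configuration.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  readr::write_csv(cohort$recordings, file.path(dir, "recordings.csv"))
  readr::write_csv(cohort$geometry, file.path(dir, "geometry.csv"))
  readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  for (k in seq_len(nrow(cohort$truth))) {
    t <- cohort$truth[k, ]
    p <- t$params[[1]]
    jsonlite::write_json(
      list(
        sample_id = t$sample_id, group = t$group, ivs_true = t$ivs_true,
        c_iso = p$c_iso,
        fibers = as.data.frame(p$fibers),
        noise_od_sd = p$noise_od_sd, noise_f_sd = p$noise_f_sd
      ),
      file.path(dir, "truth", paste0(t$sample_id, ".json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
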