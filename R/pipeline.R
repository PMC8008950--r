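#' Run the full biomechanical analysis pipeline
#'
#' End-to-end per-sample and cohort analysis of myograph recordings:
#'
#' 1. estimate each sample's in-vivo stretch (IVS) from its force-length
#'    curves and apply the axial-force QC rule to its pressure sweep;
#' 2. build circumferential (sweep at IVS) and axial (force-length at the
#'    context pressure) stress-stretch curves and their tangent moduli;
#' 3. summarise QC-passing samples into pointwise group curves;
#' 4. compare each group with the reference group: two-way ANOVA of the
#'    stress curves over pressure- or stretch-matched points, Mann-Whitney
#'    on IVS (Holm-Sidak adjusted across comparisons when more than one).
#'
#' Per-sample failures (degenerate geometry, missing tests, QC failure) are
#' quarantined with a reason and the run continues; the pipeline fails only
#' if a whole group drops out.
#'
#' @param recordings Recording table (see [read_recordings()]).
#' @param geometry Per-sample unloaded geometry (see [read_geometry()]).
#' @param metadata Per-sample metadata with `sample_id`, `group`; `NULL`
#'   puts every sample in one group `"all"` (per-sample results only).
#' @param config A [pipeline_config()].
#' @return Object of class `artery_analysis` with elements `ivs`
#'   (per-sample IVS + QC tibble), `curves`, `tangent`, `summaries`,
#'   `stats`, `exclusions`, `config`.  Supports [tidy()] and [glance()].
#' @export
run_pipeline <- function(recordings, geometry, metadata = NULL,
                         config = pipeline_config()) {
  recordings <- validate_recordings(recordings)
  if (is.null(metadata)) {
    metadata <- tibble(
      sample_id = unique(recordings$sample_id),
      group = "all"
    )
  }
  no_geo <- setdiff(unique(recordings$sample_id), geometry$sample_id)
  if (length(no_geo)) {
    abort(
      paste0(
        "samples without unloaded geometry: ",
        paste(no_geo, collapse = ", ")
      ),
      class = "arterymech_error_validation"
    )
  }
  ids <- unique(recordings$sample_id)
  per_sample <- vector("list", length(ids))
  exclusions <- tibble(sample_id = character(0), reason = character(0))
  for (k in seq_along(ids)) {
    id <- ids[k]
    res <- tryCatch(
      analyze_sample(
        recordings[recordings$sample_id == id, ],
        geometry[geometry$sample_id == id, ],
        config, id
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      exclusions <- dplyr::bind_rows(
        exclusions,
        tibble(sample_id = id, reason = conditionMessage(res))
      )
    } else {
      per_sample[[k]] <- res
    }
  }
  per_sample <- per_sample[!vapply(per_sample, is.null, logical(1))]
  if (!length(per_sample)) {
    abort("no sample could be analyzed", class = "arterymech_error_pipeline")
  }
  ivs_tbl <- purrr::map_dfr(per_sample, "ivs") |>
    dplyr::left_join(metadata, by = "sample_id")
  curves <- purrr::map_dfr(per_sample, "curves")
  tangent <- purrr::map_dfr(per_sample, "tangent")

  qc_fail <- ivs_tbl$sample_id[!ivs_tbl$qc_pass %in% TRUE]
  if (length(qc_fail)) {
    exclusions <- dplyr::bind_rows(
      exclusions,
      tibble(
        sample_id = qc_fail,
        reason = sprintf(
          "axial-force QC: spread exceeds %g or undefined",
          config$qc_threshold
        )
      )
    )
  }
  keep <- setdiff(ids, exclusions$sample_id)
  groups_all <- unique(metadata$group[metadata$sample_id %in% ids])
  groups_kept <- unique(metadata$group[metadata$sample_id %in% keep])
  lost <- setdiff(groups_all, groups_kept)
  if (length(lost)) {
    abort(
      paste0(
        "whole group(s) excluded: ",
        paste(lost, collapse = ", ")
      ),
      class = "arterymech_error_pipeline"
    )
  }

  kept_curves <- curves[curves$sample_id %in% keep, ] |>
    dplyr::left_join(metadata[, c("sample_id", "group")], by = "sample_id")
  circ <- kept_curves[kept_curves$axis == "circumferential", ]
  axial <- kept_curves[kept_curves$axis == "axial", ]

  summaries <- list(
    circumferential = summarize_curve_axis(circ, config$dispersion),
    axial = summarize_curve_axis(axial, config$dispersion)
  )

  reference <- config$reference_group %||% groups_kept[1]
  if (!reference %in% groups_kept) {
    abort(sprintf("reference group '%s' not present", reference),
      class = "arterymech_error_pipeline"
    )
  }
  others <- setdiff(groups_kept, reference)
  stats <- NULL
  if (length(others)) {
    comparisons <- purrr::map(others, function(g) {
      sel_c <- circ[circ$group %in% c(reference, g), ]
      sel_a <- axial[axial$group %in% c(reference, g), ]
      ivs_pair <- ivs_tbl[ivs_tbl$sample_id %in% keep &
        ivs_tbl$group %in% c(reference, g), ]
      # pressure-matched comparison convention: circumferential curves are
      # compared on the stretch reached at each pressure step (the
      # left-shift phenotype), axial curves on the stress at each stretch
      # step of the force-length protocol
      list(
        group = g,
        anova_circ = two_way_anova_curves(
          sel_c, .data$stretch, .data$group, .data$x_nominal
        ),
        anova_axial = two_way_anova_curves(
          sel_a, .data$stress_kpa, .data$group, .data$x_nominal
        ),
        mw_ivs = mann_whitney(ivs_pair, .data$ivs, .data$group)
      )
    })
    mw_p <- vapply(comparisons, function(cc) cc$mw_ivs$p_value, numeric(1))
    adj <- if (length(mw_p) > 1) holm_sidak(mw_p) else mw_p
    stats <- list(
      reference = reference,
      comparisons = setNames(comparisons, others),
      mw_ivs = tibble(
        group = others,
        u = vapply(comparisons, function(cc) cc$mw_ivs$statistic, numeric(1)),
        p_value = mw_p,
        p_adjusted = adj,
        stars = signif_stars(adj)
      )
    )
  }
  structure(
    list(
      ivs = ivs_tbl, curves = curves, tangent = tangent,
      summaries = summaries, stats = stats,
      exclusions = exclusions, config = config,
      reference = reference
    ),
    class = "artery_analysis"
  )
}

# Per-sample stage: IVS, QC, stress-stretch and tangent curves.
analyze_sample <- function(rec, geo_row, config, id) {
  fl <- rec[rec$test_type == "force_length", ]
  sw <- rec[rec$test_type == "pressure_sweep", ]
  if (nrow(fl) == 0) {
    abort("no force_length test", class = "arterymech_error_validation")
  }
  if (nrow(sw) == 0) {
    abort("no pressure_sweep test", class = "arterymech_error_validation")
  }
  fit <- estimate_ivs(fl)
  qc <- qc_axial_force_spread(sw,
    threshold = config$qc_threshold,
    pressure_floor = config$qc_pressure_floor
  )
  circ <- build_stress_stretch(rec, geo_row,
    axis = "circumferential",
    stretch_ref = config$stretch_ref, sample_id = id
  )
  circ$x_nominal <- circ$pressure_mmHg
  axial <- build_stress_stretch(rec, geo_row,
    axis = "axial",
    context_pressure = config$axial_context_pressure,
    stretch_ref = config$stretch_ref, sample_id = id
  )
  axial$x_nominal <- axial$stretch
  curves <- dplyr::bind_rows(circ, axial)
  tangent <- dplyr::bind_rows(
    tangent_modulus(circ,
      method = config$tangent_method,
      window = config$tangent_window
    ),
    tangent_modulus(axial,
      method = config$tangent_method,
      window = config$tangent_window
    )
  )
  list(
    ivs = tibble(
      sample_id = id, ivs = fit$ivs, spread = fit$spread,
      low_confidence = fit$low_confidence,
      qc_force_spread = qc$qc_force_spread, qc_pass = qc$qc_pass
    ),
    curves = curves,
    tangent = tangent
  )
}

summarize_curve_axis <- function(ax_curves, dispersion) {
  if (nrow(ax_curves) == 0) {
    return(tibble())
  }
  stress <- summarize_group_curves(
    ax_curves, .data$stress_kpa, .data$x_nominal, .data$group,
    dispersion = dispersion
  )
  stretch <- ax_curves |>
    dplyr::group_by(group = .data$group, x = .data$x_nominal) |>
    dplyr::summarise(stretch_mean = mean(.data$stretch), .groups = "drop")
  dplyr::left_join(stress, stretch, by = c("group", "x"))
}

#' @export
print.artery_analysis <- function(x, ...) {
  cat(
    "<artery_analysis>", nrow(x$ivs), "samples analyzed;",
    nrow(x$exclusions), "excluded\n"
  )
  cat("  reference group:", x$reference, "\n")
  if (!is.null(x$stats)) {
    cat("  IVS comparisons (Mann-Whitney, Holm-Sidak adjusted):\n")
    print(as.data.frame(x$stats$mw_ivs), row.names = FALSE)
  }
  invisible(x)
}

#' Write an analysis bundle to disk with a reproducibility manifest
#'
#' Serialises the per-sample IVS/QC table, the tidy curve and
#' tangent-modulus tables, the group summaries, the statistics (JSON), a
#' markdown run report (group summaries, tests, exclusions), and a
#' `manifest.json` listing every written file with its MD5 hash alongside
#' the configuration, seed and package version.
#'
#' @param analysis An `artery_analysis` object from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "artery_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(tbl, name) {
    p <- file.path(dir, name)
    readr::write_csv(tbl, p)
    files <<- c(files, p)
  }
  wr(analysis$ivs, "ivs.csv")
  wr(analysis$curves, "curves.csv")
  wr(analysis$tangent, "tangent_modulus.csv")
  if (nrow(analysis$summaries$circumferential)) {
    wr(analysis$summaries$circumferential, "summary_circumferential.csv")
  }
  if (nrow(analysis$summaries$axial)) {
    wr(analysis$summaries$axial, "summary_axial.csv")
  }
  wr(analysis$exclusions, "exclusions.csv")
  if (!is.null(analysis$stats)) {
    p <- file.path(dir, "stats.json")
    jsonlite::write_json(
      list(
        reference = analysis$stats$reference,
        mann_whitney_ivs = analysis$stats$mw_ivs,
        anova = lapply(analysis$stats$comparisons, function(cc) {
          list(
            group = cc$group,
            circumferential = cc$anova_circ$effects,
            axial = cc$anova_axial$effects
          )
        })
      ),
      p,
      auto_unbox = TRUE, digits = NA
    )
    files <- c(files, p)
  }
  rp <- file.path(dir, "report.md")
  writeLines(render_report(analysis), rp)
  files <- c(files, rp)
  manifest <- list(
    created = "run",
    seed = analysis$config$seed,
    config = unclass(analysis$config),
    package_version = as.character(utils::packageVersion("arterymech")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

render_report <- function(x) {
  lines <- c(
    "# Arterial biomechanics run report",
    "",
    sprintf(
      "Samples analyzed: %d; excluded: %d; reference group: %s",
      nrow(x$ivs), nrow(x$exclusions), x$reference
    ),
    "",
    "## Per-sample IVS and QC",
    "",
    knit_table(x$ivs[, c(
      "sample_id", "group", "ivs", "spread",
      "qc_force_spread", "qc_pass"
    )])
  )
  if (nrow(x$exclusions)) {
    lines <- c(
      lines, "", "## Exclusions", "",
      knit_table(x$exclusions)
    )
  }
  if (!is.null(x$stats)) {
    lines <- c(
      lines, "", "## IVS comparisons (two-tailed Mann-Whitney)", "",
      knit_table(x$stats$mw_ivs)
    )
    for (g in names(x$stats$comparisons)) {
      cc <- x$stats$comparisons[[g]]
      lines <- c(
        lines, "",
        sprintf(
          "## Two-way ANOVA vs %s: %s (circumferential)",
          x$reference, g
        ), "",
        knit_table(cc$anova_circ$effects),
        "",
        sprintf("## Two-way ANOVA vs %s: %s (axial)", x$reference, g), "",
        knit_table(cc$anova_axial$effects)
      )
    }
  }
  lines
}

# minimal pipe-table renderer (numbers to 4 significant digits)
knit_table <- function(tbl) {
  fmt <- function(v) {
    if (is.numeric(v)) signif(v, 4) else v
  }
  tbl <- as.data.frame(lapply(tbl, fmt))
  header <- paste0("| ", paste(names(tbl), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tbl)), collapse = "|"), "|")
  rows <- apply(tbl, 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(header, sep, rows)
}
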