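#' Plot force-length curves and the estimated IVS
#'
#' One line per constant pressure; the vertical line marks the estimated
#' in-vivo stretch, where the curves (nearly) intersect.
#'
#' @param data Tidy force-length recordings (`pressure_mmHg`,
#'   `axial_stretch`, `force_mN`).
#' @param ivs Optional IVS to mark (scalar or `ivs_fit`).
#' @return A ggplot object.
#' @export
plot_force_length <- function(data, ivs = NULL) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(
      x = .data$axial_stretch, y = .data$force_mN,
      colour = factor(.data$pressure_mmHg),
      group = factor(.data$pressure_mmHg)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "axial stretch (-)", y = "transducer force (mN)",
      colour = "pressure (mmHg)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(ivs)) {
    v <- if (inherits(ivs, "ivs_fit")) ivs$ivs else ivs
    p <- p + ggplot2::geom_vline(xintercept = v, linetype = "dashed")
  }
  p
}

#' Diagnostic plot of an IVS fit
#'
#' Shows the pairwise crossing stretches against the pooled estimate.
#'
#' @param object An `ivs_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ivs_fit <- function(object, ...) {
  crossings <- object$crossings[!is.na(object$crossings$stretch), ]
  ggplot2::ggplot(
    crossings,
    ggplot2::aes(
      x = .data$stretch,
      y = paste(.data$pressure_lo, "vs", .data$pressure_hi)
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$ivs, linetype = "dashed") +
    ggplot2::labs(
      x = "crossing stretch (-)", y = "pressure pair",
      title = sprintf("IVS = %.3f (spread %.3g)", object$ivs, object$spread)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-sample or group-summary stress-stretch curves
#'
#' For per-sample tidy curves (output of [build_stress_stretch()] or the
#' `curves` element of an analysis) draws one line per sample; for group
#' summaries (the `summaries` element) draws group means with dispersion
#' ribbons.
#'
#' @param curves Tidy curve tibble with `stretch`, `stress_kpa`, and either
#'   `sample_id` or (`group`, `stretch_mean`, `mean`, `disp_value`).
#' @return A ggplot object.
#' @export
plot_stress_stretch <- function(curves) {
  if (all(c("stretch_mean", "mean", "disp_value") %in% names(curves))) {
    ggplot2::ggplot(
      curves,
      ggplot2::aes(
        x = .data$stretch_mean, y = .data$mean,
        colour = .data$group, group = .data$group
      )
    ) +
      ggplot2::geom_line() +
      ggplot2::geom_pointrange(
        ggplot2::aes(
          ymin = .data$mean - .data$disp_value,
          ymax = .data$mean + .data$disp_value
        ),
        size = 0.2
      ) +
      ggplot2::labs(x = "stretch (-)", y = "Cauchy stress (kPa)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      curves,
      ggplot2::aes(
        x = .data$stretch, y = .data$stress_kpa,
        group = .data$sample_id,
        colour = if ("group" %in% names(curves)) .data$group else NULL
      )
    ) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::labs(
        x = "stretch (-)", y = "Cauchy stress (kPa)",
        colour = "group"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot tangent-modulus curves
#'
#' @param tangent Tidy tangent tibble (`stretch`, `e_tan_kpa`, `sample_id`,
#'   optionally `axis`).
#' @return A ggplot object.
#' @export
plot_tangent_modulus <- function(tangent) {
  p <- ggplot2::ggplot(
    tangent,
    ggplot2::aes(
      x = .data$stretch, y = .data$e_tan_kpa,
      group = .data$sample_id
    )
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "stretch (-)", y = "tangent modulus (kPa)") +
    ggplot2::theme_minimal()
  if ("axis" %in% names(tangent)) {
    p <- p + ggplot2::facet_wrap(~axis, scales = "free")
  }
  p
}
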