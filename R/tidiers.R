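#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: `tidy()` returns
#' the per-component table (crossings of an IVS fit, ANOVA effect rows, one
#' row per Mann-Whitney test, per-sample IVS of an analysis), `glance()` a
#' one-row model-level summary.
#'
#' @param x A fitted object (`ivs_fit`, `curve_anova`, `mw_test`,
#'   `artery_analysis`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.ivs_fit <- function(x, ...) {
  x$crossings
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.ivs_fit <- function(x, ...) {
  tibble(
    ivs = x$ivs, spread = x$spread, n_curves = x$n_curves,
    n_crossings = sum(!is.na(x$crossings$stretch)),
    low_confidence = x$low_confidence
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.curve_anova <- function(x, ...) {
  x$effects
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.curve_anova <- function(x, ...) {
  grp <- x$effects[x$effects$term == "group", ]
  tibble(
    n = x$n,
    n_groups = length(x$levels_group),
    n_positions = length(x$levels_x),
    group_statistic = grp$statistic,
    group_p_value = grp$p_value
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.mw_test <- function(x, ...) {
  tibble(
    group1 = x$groups[1], group2 = x$groups[2],
    statistic = x$statistic, p_value = x$p_value,
    mode = x$mode, stars = x$stars
  )
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.mw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value, mode = x$mode,
    n_x = x$n_x, n_y = x$n_y, ties = x$ties
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.artery_analysis <- function(x, ...) {
  x$ivs
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.artery_analysis <- function(x, ...) {
  tibble(
    n_samples = nrow(x$ivs),
    n_excluded = nrow(x$exclusions),
    n_groups = length(unique(x$ivs$group)),
    reference = x$reference
  )
}
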