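#' Significance stars at the conventional thresholds
#'
#' `***` for P < 0.001, `**` for P < 0.01, `*` for P < 0.05, empty otherwise.
#'
#' @param p Vector of p-values.
#' @return Character vector of star strings.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Pointwise group summaries of matched curves
#'
#' Summarises per-sample curves sharing a nominal x-grid (pressure steps or
#' stretch bins) into pointwise mean and dispersion per group, the form in
#' which grouped stress-stretch and geometry-versus-pressure curves are
#' reported (mean +/- SE or mean +/- SD).
#'
#' @param data Tidy per-sample values: one row per (sample, x).
#' @param response Column with the response (tidy-eval).
#' @param x Column with the matched x-grid value (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param dispersion `"se"` or `"sd"`.
#' @return Tibble with columns `group`, `x`, `n`, `mean`, `sd`, `se`,
#'   `dispersion`, `disp_value`, and `flagged` (`TRUE` where n < 2 leaves the
#'   dispersion undefined).
#' @examples
#' d <- data.frame(
#'   g = rep(c("a", "b"), each = 4),
#'   p = rep(c(10, 20), 4), y = rnorm(8)
#' )
#' summarize_group_curves(d, y, p, g)
#' @export
summarize_group_curves <- function(data, response, x, group,
                                   dispersion = c("se", "sd")) {
  dispersion <- match.arg(dispersion)
  if (nrow(data) == 0) {
    abort("empty input", class = "arterymech_error_validation")
  }
  out <- data |>
    dplyr::group_by(group = {{ group }}, x = {{ x }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ response }}),
      sd = stats::sd({{ response }}),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      dispersion = .env$dispersion,
      disp_value = if (.env$dispersion == "se") .data$se else .data$sd,
      flagged = .data$n < 2
    )
  if (any(out$flagged)) {
    warn("some grid points have n < 2; dispersion undefined there")
  }
  out
}

#' Two-way fixed-effects ANOVA over pressure- or stretch-matched curves
#'
#' Classic two-factor fixed-effects ANOVA with interaction, as applied to
#' grouped biomechanical curves: responses at matched x-points (pressure
#' steps or stretch bins) are modelled as group x position, and the group
#' main effect tests whether the curves differ overall.  Repeated points
#' within a sample are treated as the second fixed factor (no subject random
#' effect); see the methods vignette for the implications.
#'
#' Sums of squares are sequential (type I), which coincides with the classic
#' cell-mean decomposition in the balanced case.
#'
#' @param data Tidy responses: one row per (sample, x).
#' @param response,group,x Tidy-eval columns: numeric response, group factor,
#'   matched-position factor.
#' @return Object of class `curve_anova` wrapping the effects table; use
#'   [tidy()] for the per-term F statistics, degrees of freedom and p-values
#'   (with significance stars), [glance()] for a one-row summary.
#' @examples
#' d <- expand.grid(g = c("a", "b"), x = c(1, 2, 3), rep = 1:4)
#' d$y <- rnorm(nrow(d)) + (d$g == "b") * 0.5
#' tidy(two_way_anova_curves(d, y, g, x))
#' @export
two_way_anova_curves <- function(data, response, group, x) {
  df <- dplyr::transmute(
    data,
    y = {{ response }},
    group = factor({{ group }}),
    x = factor({{ x }})
  )
  if (nlevels(df$group) < 2 || nlevels(df$x) < 2) {
    abort("both factors need >= 2 levels", class = "arterymech_error_validation")
  }
  cells <- table(df$group, df$x)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(
      sprintf(
        "empty cell: group '%s' at x '%s'",
        rownames(cells)[idx[1]], colnames(cells)[idx[2]]
      ),
      class = "arterymech_error_validation"
    )
  }
  fit <- lm(y ~ group * x, data = df)
  tab <- anova(fit)
  terms <- rownames(tab)
  eff <- tibble(
    term = c("group", "x", "group:x", "residuals"),
    df = tab$Df[match(c("group", "x", "group:x", "Residuals"), terms)],
    sumsq = tab$`Sum Sq`[match(c("group", "x", "group:x", "Residuals"), terms)],
    statistic = tab$`F value`[match(c("group", "x", "group:x", "Residuals"), terms)],
    p_value = tab$`Pr(>F)`[match(c("group", "x", "group:x", "Residuals"), terms)]
  )
  eff$stars <- signif_stars(eff$p_value)
  structure(
    list(
      effects = eff,
      n = nrow(df),
      levels_group = levels(df$group),
      levels_x = levels(df$x),
      fit = fit
    ),
    class = "curve_anova"
  )
}

#' @export
print.curve_anova <- function(x, ...) {
  cat(
    "<curve_anova> two-way fixed-effects ANOVA,", x$n, "observations;",
    length(x$levels_group), "groups x", length(x$levels_x), "positions\n"
  )
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two samples.  In `"exact"` mode (automatic when
#' the combined sample size is at most 16 and there are no ties) the null
#' distribution of U is built by full enumeration of all rank arrangements
#' and the two-tailed p-value is `min(1, 2 min(P(U <= u), P(U >= u)))`.
#' Otherwise a normal approximation with mid-rank tie correction and
#' continuity correction is used; ties always force the approximation (with
#' a note).
#'
#' @param data Data frame holding the two samples in long form.
#' @param value Tidy-eval column with the measured values.
#' @param group Tidy-eval column with exactly two group labels.
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @param exact_max Largest combined sample size for which `"auto"` chooses
#'   enumeration.
#' @return Object of class `mw_test` with U statistic (pairs where the first
#'   group exceeds the second, ties counted half), the two-tailed p-value,
#'   the mode used, and group sizes.  Supports [tidy()] and [glance()].
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' mann_whitney(d, v, g) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(data, value, group, mode = c("auto", "exact", "approx"),
                         exact_max = 16) {
  mode <- match.arg(mode)
  df <- dplyr::transmute(data, value = {{ value }}, group = {{ group }})
  if (anyNA(df)) {
    abort("missing values not supported", class = "arterymech_error_validation")
  }
  lev <- unique(df$group)
  if (length(lev) != 2) {
    abort("mann_whitney needs exactly two groups",
      class = "arterymech_error_validation"
    )
  }
  x <- df$value[df$group == lev[1]]
  y <- df$value[df$group == lev[2]]
  if (!length(x) || !length(y)) {
    abort("both samples must be non-empty", class = "arterymech_error_validation")
  }
  nx <- length(x)
  ny <- length(y)
  nn <- nx + ny
  r <- rank(c(x, y)) # mid-ranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- any(duplicated(c(x, y)))
  if (mode == "exact" && has_ties) {
    inform("ties present: exact enumeration unavailable, using approximation")
  }
  use_exact <- switch(mode,
    exact = !has_ties,
    approx = FALSE,
    auto = !has_ties && nn <= exact_max
  )
  if (use_exact) {
    # full enumeration of all C(n, nx) rank arrangements
    combs <- combn(nn, nx)
    u_all <- colSums(matrix(seq_len(nn)[combs], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
    mode_used <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    tie_corr <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma2 <- nx * ny / 12 * ((nn + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    mode_used <- "approx"
  }
  structure(
    list(
      statistic = u, p_value = p, mode = mode_used,
      n_x = nx, n_y = ny,
      groups = as.character(lev), ties = has_ties,
      stars = signif_stars(p)
    ),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(
    "<mw_test> two-tailed Mann-Whitney (", x$mode, "): U =", x$statistic,
    ", p =", format(x$p_value, digits = 4), x$stars, "\n"
  )
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Step-down Sidak adjustment of a family of p-values: with the p-values
#' sorted increasingly, the i-th is adjusted to `1 - (1 - p_(i))^(m - i + 1)`,
#' monotonicity is enforced by a running maximum, and the adjusted values are
#' returned in the original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, same order as the input.
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.30))
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "arterymech_error_validation")
  }
  m <- length(p)
  if (m <= 1) {
    return(p)
  }
  o <- order(p)
  ps <- p[o]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}
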