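#' Intersection of two force-length curves
#'
#' Piecewise-linear interpolation of two force-stretch curves recorded at
#' different constant pressures; returns the stretch at which their
#' difference crosses zero.  If several zeros exist, the physically expected
#' crossover is preferred: the one where the higher-pressure curve passes
#' from below to above the lower-pressure curve; failing that, the zero
#' closest to the midpoint of the shared stretch span.  Returns `NA` when
#' the curves do not cross within the overlap.
#'
#' @param a,b Data frames with columns `axial_stretch`, `force_mN` and a
#'   constant `pressure_mmHg` column (one force-length curve each).
#' @return The crossing stretch (scalar), or `NA_real_`.
#' @examples
#' a <- data.frame(pressure_mmHg = 90, axial_stretch = c(1, 2), force_mN = c(0, 10))
#' b <- data.frame(pressure_mmHg = 120, axial_stretch = c(1, 2), force_mN = c(-6.4, 11.6))
#' pairwise_intersection(a, b) # lines cross at 1.8
#' @export
pairwise_intersection <- function(a, b) {
  a <- validate_fl_curve(a)
  b <- validate_fl_curve(b)
  # orient so that `hi` is the higher-pressure curve
  if (a$pressure_mmHg[1] > b$pressure_mmHg[1]) {
    tmp <- a
    a <- b
    b <- tmp
  }
  lo_span <- range(a$axial_stretch)
  hi_span <- range(b$axial_stretch)
  span <- c(max(lo_span[1], hi_span[1]), min(lo_span[2], hi_span[2]))
  if (span[1] >= span[2]) {
    abort("force-length curves share no overlapping stretch span",
      class = "arterymech_error_validation"
    )
  }
  knots <- sort(unique(c(
    a$axial_stretch[a$axial_stretch >= span[1] & a$axial_stretch <= span[2]],
    b$axial_stretch[b$axial_stretch >= span[1] & b$axial_stretch <= span[2]],
    span
  )))
  fa <- approx(a$axial_stretch, a$force_mN, xout = knots)$y
  fb <- approx(b$axial_stretch, b$force_mN, xout = knots)$y
  d <- fb - fa # higher-pressure minus lower-pressure
  roots <- numeric(0)
  rising <- logical(0)
  for (i in seq_len(length(knots) - 1)) {
    d1 <- d[i]
    d2 <- d[i + 1]
    if (d1 == 0 && i == 1) {
      roots <- c(roots, knots[i])
      rising <- c(rising, d2 > 0)
    }
    if (d2 == 0) {
      roots <- c(roots, knots[i + 1])
      rising <- c(rising, d1 < 0)
    } else if (d1 * d2 < 0) {
      roots <- c(roots, knots[i] - d1 * (knots[i + 1] - knots[i]) / (d2 - d1))
      rising <- c(rising, d1 < 0)
    }
  }
  if (!length(roots)) {
    return(NA_real_)
  }
  if (any(rising)) {
    roots <- roots[rising]
  }
  roots[which.min(abs(roots - mean(span)))]
}

validate_fl_curve <- function(x) {
  need <- c("pressure_mmHg", "axial_stretch", "force_mN")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste("force-length curve missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  x <- as_tibble(x)[order(x$axial_stretch), ]
  if (nrow(x) < 2 || any(diff(x$axial_stretch) <= 0)) {
    abort("force-length curve needs >= 2 strictly increasing stretches",
      class = "arterymech_error_validation"
    )
  }
  if (length(unique(x$pressure_mmHg)) != 1) {
    abort("a force-length curve must be recorded at a single pressure",
      class = "arterymech_error_validation"
    )
  }
  x
}

#' Estimate the in-vivo axial stretch (IVS) from force-length tests
#'
#' The in-vivo stretch is the axial stretch at which a vessel's transducer
#' force is insensitive to lumen pressure; it is estimated as the common
#' intersection of the force-stretch curves recorded at two or more constant
#' pressures.  All pairwise curve intersections are located by
#' piecewise-linear interpolation ([pairwise_intersection()]) and averaged;
#' the maximum absolute deviation of the individual crossings from that mean
#' is retained as a diagnostic spread.
#'
#' With three or more curves, a result based on fewer than two usable
#' crossings is flagged `low_confidence` rather than dropped.
#'
#' @param data Tidy force-length recordings for one sample: columns
#'   `pressure_mmHg`, `axial_stretch`, `force_mN`, with >= 2 distinct
#'   pressures.
#' @return An object of class `ivs_fit`: list with elements `ivs`,
#'   `crossings` (tibble `pressure_lo`, `pressure_hi`, `stretch`), `spread`,
#'   `n_curves`, `low_confidence`.  Supports [tidy()], [glance()] and
#'   `print()`.
#' @examples
#' fl <- synth_force_length_curves(ivs = 1.8)
#' estimate_ivs(fl)
#' @export
estimate_ivs <- function(data) {
  need <- c("pressure_mmHg", "axial_stretch", "force_mN")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  pressures <- sort(unique(data$pressure_mmHg))
  if (length(pressures) < 2) {
    abort("IVS estimation needs force-length curves at >= 2 distinct pressures",
      class = "arterymech_error_validation"
    )
  }
  curves <- lapply(pressures, function(p) data[data$pressure_mmHg == p, ])
  pairs <- combn(length(pressures), 2)
  crossings <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    tibble(
      pressure_lo = pressures[i1],
      pressure_hi = pressures[i2],
      stretch = pairwise_intersection(curves[[i1]], curves[[i2]])
    )
  })
  usable <- crossings$stretch[!is.na(crossings$stretch)]
  if (!length(usable)) {
    abort("no pair of force-length curves crosses; IVS undefined",
      class = "arterymech_error_ivs"
    )
  }
  low_conf <- length(pressures) >= 3 && length(usable) < 2
  if (low_conf) {
    warn("fewer than 2 usable crossings among >= 3 curves; IVS flagged low-confidence")
  }
  ivs <- mean(usable)
  structure(
    list(
      ivs = ivs,
      crossings = crossings,
      spread = max(abs(usable - ivs)),
      n_curves = length(pressures),
      low_confidence = low_conf
    ),
    class = "ivs_fit"
  )
}

#' @export
print.ivs_fit <- function(x, ...) {
  cat(
    "<ivs_fit> IVS =", format(x$ivs, digits = 5),
    "from", x$n_curves, "curves; crossing spread",
    format(x$spread, digits = 3),
    if (x$low_confidence) "(LOW CONFIDENCE)" else "", "\n"
  )
  invisible(x)
}

#' Axial-force quality control over the pressure sweep
#'
#' Validity check of an IVS determination: during the pressure sweep
#' performed at the estimated IVS, the recorded axial force should stay
#' close to its across-pressure mean.  The spread statistic is
#' `max_P |f(P) - mean(f)| / mean(f)` over the retained pressure steps, and
#' the sample passes when it does not exceed `threshold` (default 0.25, the
#' conventional 25% exclusion rule).  Steps below `pressure_floor` (default
#' 20 mmHg) are excluded from the statistic, where near-zero forces make the
#' relative deviation unstable.
#'
#' @param sweep Pressure-sweep rows for one sample: columns `pressure_mmHg`,
#'   `force_mN`.
#' @param threshold Maximum tolerated relative force spread.
#' @param pressure_floor Minimum pressure (mmHg) of steps entering the
#'   statistic.
#' @return One-row tibble with `qc_force_spread` and `qc_pass`.  When the
#'   mean retained force is not positive the spread is undefined: both are
#'   `NA` and a warning flags the sample.
#' @examples
#' sw <- data.frame(pressure_mmHg = seq(0, 140, 10), force_mN = 5)
#' qc_axial_force_spread(sw)
#' @export
qc_axial_force_spread <- function(sweep, threshold = 0.25,
                                  pressure_floor = 20) {
  need <- c("pressure_mmHg", "force_mN")
  miss <- setdiff(need, names(sweep))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  f <- sweep$force_mN[sweep$pressure_mmHg >= pressure_floor]
  if (!length(f)) {
    abort("no pressure steps at or above the pressure floor",
      class = "arterymech_error_validation"
    )
  }
  mu <- mean(f)
  if (mu <= 0) {
    warn("mean axial force <= 0: QC spread undefined, sample flagged")
    return(tibble(qc_force_spread = NA_real_, qc_pass = NA))
  }
  spread <- max(abs(f - mu)) / mu
  tibble(qc_force_spread = spread, qc_pass = spread <= threshold)
}
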