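#' Tangent modulus of a stress-stretch curve
#'
#' Pointwise stiffness `E_tan = d sigma / d lambda` of a stress-stretch
#' curve.  The default `"window"` method fits a local least-squares line over
#' a sliding window of `window` points (odd, default 5) centred on each
#' interior point and reports its slope; points nearer the ends than half a
#' window use the corresponding one-sided window.  The `"central"` method
#' uses three-point central differences on the (possibly non-uniform) grid,
#' with one-sided differences at the two endpoints.
#'
#' Input points are sorted by stretch before differentiation, so the result
#' is invariant to row order.  If the curve has fewer points than the
#' requested window, the window is shrunk to the largest odd size that fits
#' and a warning is raised.
#'
#' @param curve Data frame with columns `stretch` and `stress_kpa` (extra
#'   columns such as `sample_id`/`axis` are carried through).
#' @param method `"window"` (sliding local linear fit) or `"central"`
#'   (finite differences).
#' @param window Odd window width in points for the `"window"` method.
#' @return Tibble with columns `stretch` and `e_tan_kpa` (plus carried
#'   identifier columns), one row per input point.
#' @examples
#' cv <- data.frame(stretch = seq(1, 2, 0.1), stress_kpa = seq(1, 2, 0.1) * 3)
#' tangent_modulus(cv) # slope 3 everywhere
#' @export
tangent_modulus <- function(curve, method = c("window", "central"),
                            window = 5) {
  method <- match.arg(method)
  need <- c("stretch", "stress_kpa")
  miss <- setdiff(need, names(curve))
  if (length(miss)) {
    abort(paste("missing columns:", paste(miss, collapse = ", ")),
      class = "arterymech_error_validation"
    )
  }
  curve <- as_tibble(curve)[order(curve$stretch), ]
  n <- nrow(curve)
  if (n < 3) {
    abort("tangent modulus needs at least 3 points",
      class = "arterymech_error_validation"
    )
  }
  x <- curve$stretch
  y <- curve$stress_kpa
  if (method == "window") {
    if (window %% 2 == 0 || window < 3) {
      abort("window must be an odd integer >= 3",
        class = "arterymech_error_validation"
      )
    }
    if (window > n) {
      window <- if (n %% 2 == 1) n else n - 1
      warn(sprintf(
        "fewer points than requested window; window shrunk to %d", window
      ))
    }
    half <- (window - 1) %/% 2
    slope <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - half)
      hi <- min(n, i + half)
      # one-sided near the ends: keep the window size by shifting it inward
      if (hi - lo + 1 < window) {
        if (lo == 1) hi <- min(n, window) else lo <- max(1, n - window + 1)
      }
      xi <- x[lo:hi]
      yi <- y[lo:hi]
      sum((xi - mean(xi)) * (yi - mean(yi))) / sum((xi - mean(xi))^2)
    }, numeric(1))
  } else {
    slope <- numeric(n)
    # non-uniform central difference on interior points
    for (i in 2:(n - 1)) {
      h1 <- x[i] - x[i - 1]
      h2 <- x[i + 1] - x[i]
      slope[i] <- (h1^2 * y[i + 1] - h2^2 * y[i - 1] +
        (h2^2 - h1^2) * y[i]) / (h1 * h2 * (h1 + h2))
    }
    slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
    slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  }
  out <- curve
  out$stress_kpa <- NULL
  out$e_tan_kpa <- slope
  out
}
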