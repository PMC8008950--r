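# Shared fixtures.  Ground truths are cached per session because computing
# the operational IVS (fine-grid force-spread scan) is the expensive step.
.fixture_cache <- new.env(parent = emptyenv())

cached_truth <- function(preset = "control") {
  key <- paste0("truth_", preset)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- artery_ground_truth(artery_params(preset))
  }
  .fixture_cache[[key]]
}

default_unloaded_df <- function(truth = cached_truth()) {
  tibble::tibble(
    unloaded_od_um = 2 * truth$unloaded$R_o,
    unloaded_h_um = truth$unloaded$H
  )
}

# One-sample recording table (noiseless unless stated) in the package format.
sample_recording <- function(truth = cached_truth(), noise = FALSE,
                             seed = 1, sweep_step = 10,
                             stretch_grid = seq(1.4, 2.1, by = 0.1)) {
  fl <- simulate_force_length_test(truth,
    stretch_grid = stretch_grid,
    noise = noise, seed = seed
  )
  sw <- simulate_pressure_sweep(truth,
    step = sweep_step, noise = noise,
    seed = seed + 1
  )
  dplyr::bind_rows(
    dplyr::mutate(fl, test_type = "force_length"),
    dplyr::mutate(sw, test_type = "pressure_sweep")
  ) |>
    dplyr::mutate(sample_id = "s1") |>
    dplyr::select(
      sample_id, test_type, pressure_mmHg, axial_stretch,
      outer_diameter_um, force_mN
    )
}

# Small two-group cohort for pipeline tests.
small_cohort <- function(n = 3, seed = 5) {
  generate_cohort(cohort_config(
    groups = tibble::tibble(
      group = c("control", "stiff"),
      n = c(n, n),
      preset = c("control", "stiff"),
      multiplier = c(1, 1),
      ivs_target = c(NA_real_, NA_real_)
    ),
    seed = seed
  ))
}

# Independent brute-force two-tailed Mann-Whitney by enumeration of all
# rank arrangements (used as the oracle for the exact mode).
mw_enum_oracle <- function(x, y) {
  nx <- length(x)
  nn <- nx + length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nn, nx)
  u_all <- colSums(matrix(seq_len(nn)[combs], nrow = nx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
}

# Independent two-way ANOVA via explicit least-squares projections onto
# nested design spaces (sequential sums of squares), no lm()/aov().
anova_projection_oracle <- function(y, a, b) {
  a <- factor(a)
  b <- factor(b)
  X0 <- matrix(1, length(y), 1)
  Xa <- stats::model.matrix(~ 0 + a)
  Xb <- stats::model.matrix(~ 0 + b)
  Xab <- stats::model.matrix(~ 0 + a:b)
  proj <- function(X) {
    q <- qr(X)
    fitted <- qr.fitted(q, y)
    fitted
  }
  ss <- function(v) sum(v^2)
  f0 <- proj(X0)
  fa <- proj(cbind(X0, Xa))
  fb <- proj(cbind(X0, Xa, Xb))
  fab <- proj(cbind(X0, Xa, Xb, Xab))
  ss_a <- ss(fa - f0)
  ss_b <- ss(fb - fa)
  ss_ab <- ss(fab - fb)
  ss_res <- ss(y - fab)
  df_a <- nlevels(a) - 1
  df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_res <- length(y) - nlevels(a) * nlevels(b)
  ms_res <- ss_res / df_res
  f_of <- function(ssq, df) (ssq / df) / ms_res
  list(
    sumsq = c(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res),
    statistic = c(
      a = f_of(ss_a, df_a), b = f_of(ss_b, df_b),
      ab = f_of(ss_ab, df_ab)
    ),
    p = c(
      a = stats::pf(f_of(ss_a, df_a), df_a, df_res, lower.tail = FALSE),
      b = stats::pf(f_of(ss_b, df_b), df_b, df_res, lower.tail = FALSE),
      ab = stats::pf(f_of(ss_ab, df_ab), df_ab, df_res, lower.tail = FALSE)
    )
  )
}

# Symmetric force trace with exact mean `mu` and exact relative spread `s`.
qc_trace <- function(s, mu = 5, n = 15, p_max = 140) {
  stopifnot(n >= 4)
  f <- rep(mu, n)
  f[n - 1] <- mu * (1 + s)
  f[n] <- mu * (1 - s)
  tibble::tibble(pressure_mmHg = seq(0, p_max, length.out = n), force_mN = f)
}
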