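test_that("group curve summaries report mean, SD and SE per point", {
  withr::local_seed(1)
  d <- expand.grid(sample = 1:6, g = c("a", "b"), p = seq(0, 40, 20))
  d$y <- rnorm(nrow(d), mean = 10)
  s <- summarize_group_curves(d, y, p, g, dispersion = "se")
  expect_equal(nrow(s), 6)
  expect_equal(s$se, s$sd / sqrt(s$n), tolerance = 1e-12)
  expect_equal(s$disp_value, s$se)
  s2 <- summarize_group_curves(d, y, p, g, dispersion = "sd")
  expect_equal(s2$disp_value, s2$sd)
  expect_error(summarize_group_curves(d[0, ], y, p, g),
    class = "arterymech_error_validation"
  )
})

test_that("singleton groups are flagged with undefined dispersion", {
  d <- data.frame(g = "a", p = c(1, 2), y = c(5, 7))
  expect_warning(s <- summarize_group_curves(d, y, p, g), regexp = "n < 2")
  expect_equal(s$mean, c(5, 7))
  expect_true(all(is.na(s$sd)))
  expect_true(all(s$flagged))
})

test_that("pointwise SD estimates are consistent with the injected noise", {
  withr::local_seed(33)
  s_true <- 1.7
  n <- 6
  pts <- 40
  d <- expand.grid(sample = seq_len(n), p = seq_len(pts))
  d$g <- "a"
  d$y <- rnorm(nrow(d), sd = s_true)
  s <- summarize_group_curves(d, y, p, g)
  # sum over points of (n-1) s_hat^2 / s^2 ~ chi-square with pts*(n-1) df
  stat <- sum((n - 1) * s$sd^2 / s_true^2)
  df <- pts * (n - 1)
  expect_gt(stat, stats::qchisq(0.001, df))
  expect_lt(stat, stats::qchisq(0.999, df))
})

test_that("additive two-factor data has zero interaction sum of squares", {
  d <- expand.grid(g = c("a", "b"), x = c("1", "2"), rep = 1:3)
  d$y <- 2 * (d$g == "b") + 5 * (d$x == "2") # purely additive, no noise
  # perfect fit: F-values are meaningless here, only the SS decomposition
  fit <- suppressWarnings(two_way_anova_curves(d, y, g, x))
  eff <- tidy(fit)
  expect_lt(eff$sumsq[eff$term == "group:x"], 1e-20)
  expect_equal(eff$sumsq[eff$term == "residuals"], 0, tolerance = 1e-20)
})

test_that("ANOVA matches an independent projection oracle to 1e-8", {
  withr::local_seed(8)
  for (r in 1:5) {
    d <- expand.grid(g = c("a", "b", "c"), x = paste0("x", 1:4), rep = 1:4)
    d$y <- rnorm(nrow(d)) + as.integer(d$g) * 0.4 + as.integer(d$x) * 0.2
    fit <- two_way_anova_curves(d, y, g, x)
    eff <- tidy(fit)
    oracle <- anova_projection_oracle(d$y, d$g, d$x)
    expect_equal(eff$sumsq, unname(oracle$sumsq), tolerance = 1e-8)
    expect_equal(eff$statistic[1:3], unname(oracle$statistic), tolerance = 1e-8)
    expect_equal(eff$p_value[1:3], unname(oracle$p), tolerance = 1e-8)
  }
})

test_that("ANOVA respects shift and scale invariance of F", {
  withr::local_seed(9)
  d <- expand.grid(g = c("a", "b"), x = paste0("x", 1:5), rep = 1:4)
  d$y <- rnorm(nrow(d)) + (d$g == "b") * 0.6
  f0 <- tidy(two_way_anova_curves(d, y, g, x))$statistic[1]
  d$y2 <- d$y + 1000
  expect_equal(tidy(two_way_anova_curves(d, y2, g, x))$statistic[1], f0,
    tolerance = 1e-8
  )
  d$y3 <- d$y * 37
  expect_equal(tidy(two_way_anova_curves(d, y3, g, x))$statistic[1], f0,
    tolerance = 1e-8
  )
})

test_that("ANOVA rejects empty cells by name", {
  d <- expand.grid(g = c("a", "b"), x = c("1", "2"), rep = 1:2)
  d$y <- rnorm(nrow(d))
  d <- d[!(d$g == "b" & d$x == "2"), ]
  err <- tryCatch(two_way_anova_curves(d, y, g, x), error = function(e) e)
  expect_s3_class(err, "arterymech_error_validation")
  expect_match(conditionMessage(err), "b")
})

test_that("the canonical separated samples give U = 0, exact p = 0.1", {
  d <- data.frame(v = 1:6, g = rep(c("a", "b"), each = 3))
  mw <- mann_whitney(d, v, g)
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1, tolerance = 1e-12)
  expect_equal(mw$mode, "exact")
})

test_that("identical samples give p = 1", {
  d <- data.frame(
    v = rep(c(1, 2, 3), 2),
    g = rep(c("a", "b"), each = 3)
  )
  mw <- suppressMessages(mann_whitney(d, v, g))
  expect_equal(mw$p_value, 1)
  expect_equal(mw$mode, "approx") # ties force the approximation
})

test_that("exact mode equals brute-force enumeration up to 8 + 8", {
  withr::local_seed(13)
  for (nx in c(2, 4, 6, 8)) {
    for (ny in c(3, 5, 8)) {
      x <- sample(1000, nx)
      y <- sample(2000:3000, ny)
      d <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(nx, ny)))
      mw <- mann_whitney(d, v, g, mode = "exact")
      expect_equal(mw$p_value, mw_enum_oracle(x, y), tolerance = 1e-12)
      # cross-check against the independent base-R implementation
      wt <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(mw$p_value, wt$p.value, tolerance = 1e-12)
      expect_equal(mw$statistic, unname(wt$statistic))
    }
  }
})

test_that("normal approximation tracks the exact p-value at n = 8 + 8", {
  withr::local_seed(17)
  for (r in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8, mean = 0.5)
    d <- data.frame(v = c(x, y), g = rep(c("a", "b"), each = 8))
    pe <- mann_whitney(d, v, g, mode = "exact")$p_value
    pa <- mann_whitney(d, v, g, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("mann_whitney validates its inputs", {
  expect_error(
    mann_whitney(data.frame(v = 1:3, g = "a"), v, g),
    class = "arterymech_error_validation"
  )
  expect_error(
    mann_whitney(data.frame(v = c(1, NA), g = c("a", "b")), v, g),
    class = "arterymech_error_validation"
  )
})

test_that("Holm-Sidak follows the step-down formula", {
  expect_equal(holm_sidak(0.2), 0.2)
  p <- c(0.01, 0.04, 0.30)
  expected <- c(1 - 0.99^3, max(1 - 0.99^3, 1 - 0.96^2), 0.30)
  expect_equal(holm_sidak(p), expected, tolerance = 1e-12)
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  expect_error(holm_sidak(c(0.5, 1.2)), class = "arterymech_error_validation")
})

test_that("adjusted p-values are monotone and never below raw ones", {
  withr::local_seed(19)
  for (r in 1:20) {
    p <- runif(sample(2:10, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(
    signif_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
    c("***", "**", "*", "", NA)
  )
})
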