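# RD estimation core: kernels, side fits vs closed-form oracles, composites,
# estimator invariances, sensitivity sweeps

test_that("kernel weights: apex, support boundary, midpoint, validation", {
  tri <- kernel_spec("triangular", 7)
  expect_equal(kernel_weight(65.0, 65, tri), 1.0)
  expect_equal(kernel_weight(72.0, 65, tri), 0.0)
  expect_equal(kernel_weight(68.5, 65, tri), 0.5)
  uni <- kernel_spec("uniform", 7)
  expect_equal(kernel_weight(c(58.1, 65, 71.9, 72), 65, uni), c(1, 1, 1, 0))
  expect_error(kernel_spec("triangular", 0), "positive")
  expect_error(kernel_spec("triangular", -2), "positive")
})

test_that("fit_side: constant outcome gives exact intercept with zero variance", {
  x <- c(60, 61, 62, 63, 66, 67, 68)
  coh <- hand_cohort(x, rep(1, length(x)))
  coh$records$rrt <- 0L
  coh$records$age <- 0.3
  for (side in c("below", "above")) {
    f <- fit_side(coh, "age", side, 65, kernel_spec("triangular", 7), 1)
    expect_equal(f$coef[1], 0.3, tolerance = 1e-12)
    expect_equal(f$coef[2], 0, tolerance = 1e-12)
    expect_equal(f$var_intercept, 0, tolerance = 1e-20)
  }
})

test_that("fit_side matches the independent normal-equations OLS oracle", {
  # 12 hand-listed points below the cutoff
  x <- c(58.2, 59.1, 59.8, 60.5, 61.3, 61.9, 62.4, 63.0, 63.6, 64.1, 64.5, 64.9)
  y <- c(0.21, 0.25, 0.19, 0.30, 0.28, 0.33, 0.27, 0.35, 0.31, 0.38, 0.36, 0.40)
  coh <- hand_cohort(x, rep(0, 12))
  coh$records$age <- y
  f <- fit_side(coh, "age", "below", 65, kernel_spec("uniform", 7), 1,
                vce = "ols")
  expect_equal(f$coef, ols_oracle(x, y, 65, 1), tolerance = 1e-10,
               ignore_attr = TRUE)
  # quadratic order as well
  f2 <- fit_side(coh, "age", "below", 65, kernel_spec("uniform", 7), 2)
  expect_equal(f2$coef, ols_oracle(x, y, 65, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("fit_side enforces the p + 2 support boundary", {
  x <- c(62, 63, 64.5)  # 3 points: enough for p=1, not for p=2
  coh <- hand_cohort(x, c(0, 1, 0))
  expect_silent(fit_side(coh, "primary", "below", 65,
                         kernel_spec("uniform", 7), 1))
  expect_error(fit_side(coh, "primary", "below", 65,
                        kernel_spec("uniform", 7), 2),
               "insufficient support on the below side")
  expect_error(fit_side(coh, "primary", "above", 65,
                        kernel_spec("uniform", 7), 1),
               "insufficient support on the above side")
})

test_that("composite outcomes follow the flag definitions", {
  df <- data.frame(rrt = c(0, 0, 0, 1), icu_transfer = c(1, 0, 0, 0),
                   arrest = c(0, 0, 0, 1), death = c(0, 1, 0, 0))
  expect_equal(composite_outcome(df, "primary"), c(1L, 0L, 0L, 1L))
  expect_equal(composite_outcome(df, "secondary"), c(1L, 1L, 0L, 1L))
  expect_error(composite_outcome(df[, -1], "primary"), "rrt")
  expect_error(rddalert:::outcome_vector(hand_cohort(c(60, 70), c(0, 1)),
                                         "nonesuch"),
               "unknown outcome label")
})

test_that("rd_estimate recovers a pure step function exactly", {
  set.seed(1)
  x <- round(runif(200, 50, 80), 1)
  coh <- hand_cohort(x, as.integer(x >= 65))
  fit <- rd_estimate(coh, "primary", 65, kernel_spec("triangular", 7))
  expect_equal(fit$estimate, 1.0, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 0)
})

test_that("uniform-kernel rd_estimate equals the difference of oracle OLS intercepts", {
  set.seed(42)
  x <- round(runif(80, 55, 75), 1)
  y <- rbinom(80, 1, 0.3 + 0.01 * (x - 65) - 0.1 * (x >= 65))
  coh <- hand_cohort(x, y)
  fit <- rd_estimate(coh, "primary", 65, kernel_spec("uniform", 7), 1)
  w <- as.numeric(abs(x - 65) < 7)
  oracle_below <- wls_oracle(x[x < 65], y[x < 65], w[x < 65], 65, 1)
  oracle_above <- wls_oracle(x[x >= 65], y[x >= 65], w[x >= 65], 65, 1)
  expect_equal(fit$estimate, oracle_above[1] - oracle_below[1],
               tolerance = 1e-10)
  # triangular kernel against the closed-form weighted solve
  tri <- kernel_spec("triangular", 7)
  fit_t <- rd_estimate(coh, "primary", 65, tri, 1)
  wt <- kernel_weight(x, 65, tri)
  tb <- wls_oracle(x[x < 65], y[x < 65], wt[x < 65], 65, 1)
  ta <- wls_oracle(x[x >= 65], y[x >= 65], wt[x >= 65], 65, 1)
  expect_equal(fit_t$estimate, ta[1] - tb[1], tolerance = 1e-10)
})

test_that("rd_fit invariants: CI brackets the estimate, p/CI duality, side counts", {
  coh <- generate_cohort(small_config(n = 6000, seed = 31))
  for (h in c(3, 7, 12)) {
    fit <- rd_estimate(coh, "primary", spec = kernel_spec("triangular", h))
    expect_lte(fit$ci_low, fit$estimate)
    expect_gte(fit$ci_high, fit$estimate)
    expect_true(fit$p_value >= 0 && fit$p_value <= 1)
    rejected <- fit$p_value < fit$alpha
    outside <- fit$ci_low > 0 || fit$ci_high < 0
    expect_equal(rejected, outside)
    expect_gte(fit$n_left, 3)
    expect_gte(fit$n_right, 3)
  }
})

test_that("records at or beyond the bandwidth carry zero weight and can be dropped", {
  coh <- generate_cohort(small_config(n = 5000, seed = 17))
  spec <- kernel_spec("triangular", 7)
  fit_all <- rd_estimate(coh, "primary", spec = spec)
  trimmed <- coh
  trimmed$records <- coh$records[abs(coh$records$max_score - 65) < 7, ]
  fit_trim <- rd_estimate(trimmed, "primary", spec = spec)
  for (fld in c("estimate", "se", "ci_low", "ci_high", "p_value",
                "n_left", "n_right")) {
    expect_equal(fit_all[[fld]], fit_trim[[fld]], tolerance = 1e-12)
  }
})

test_that("rd_estimate is invariant under a common shift of scores and cutoff", {
  coh <- generate_cohort(small_config(n = 5000, seed = 23))
  fit <- rd_estimate(coh, "primary", 65, kernel_spec("triangular", 7))
  shifted <- coh
  shifted$records$max_score <- coh$records$max_score + 10
  shifted$threshold <- 75
  fit_s <- rd_estimate(shifted, "primary", 75, kernel_spec("triangular", 7))
  expect_equal(fit$estimate, fit_s$estimate, tolerance = 1e-9)
  expect_equal(fit$se, fit_s$se, tolerance = 1e-9)
})

test_that("missing outcomes are excluded with a message", {
  coh <- generate_cohort(small_config(n = 3000, seed = 5,
                                      missing_covariate_rate = 0.1))
  expect_message(rd_estimate(coh, "age", spec = kernel_spec("triangular", 10)),
                 "excluding")
})

test_that("bandwidth_sweep matches direct estimates and skips unusable bandwidths", {
  coh <- generate_cohort(small_config(n = 6000, seed = 19))
  sw <- bandwidth_sweep(coh, "primary", h_values = 1:15)
  expect_equal(sw$h, as.numeric(1:15))
  direct <- rd_estimate(coh, "primary", spec = kernel_spec("triangular", 7))
  entry <- sw$fits[[which(sw$h == 7)]]
  for (fld in c("estimate", "se", "ci_low", "ci_high", "p_value",
                "bandwidth", "n_left", "n_right")) {
    expect_identical(entry[[fld]], direct[[fld]])
  }
  # a bandwidth too narrow to support the fit is skipped with a warning
  sparse <- hand_cohort(c(55, 60, 64.9, 65.1, 70, 75), c(0, 0, 1, 1, 0, 1))
  expect_warning(sw2 <- bandwidth_sweep(sparse, "primary",
                                        h_values = c(0.5, 20)),
                 "skipped")
  expect_equal(sw2$h, 20)
  expect_equal(sw2$skipped, 0.5)
})

test_that("stable estimates across bandwidths when the truth is globally linear", {
  # linear baseline with a constant jump: every bandwidth estimates the same
  # quantity, so the spread across h stays within the pooled uncertainty
  cfg <- small_config(n = 20000, seed = 77)
  coh <- generate_cohort(cfg)
  df <- coh$records
  set.seed(99)
  df$age <- 2 + 0.1 * df$max_score + 5 * (df$max_score >= 65) +
    rnorm(nrow(df), 0, 3)
  coh$records <- df
  sw <- bandwidth_sweep(coh, "age", h_values = c(3, 5, 7, 9, 11, 13, 15))
  est <- vapply(sw$fits, function(f) f$estimate, numeric(1))
  ses <- vapply(sw$fits, function(f) f$se, numeric(1))
  expect_lt(max(est) - min(est), 2 * sqrt(sum(ses^2) / length(ses)))
  ciw <- vapply(sw$fits, function(f) f$ci_high - f$ci_low, numeric(1))
  expect_true(all(diff(ciw) <= 1e-9))
})
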