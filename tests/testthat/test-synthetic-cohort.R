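# synthetic cohort generator: conservation, calibration, reproducibility,
# null smoothness, manipulation bookkeeping, trajectory censoring

test_that("generate_cohort conserves n, hits the above-threshold fraction, and is reproducible", {
  cfg <- cohort_config(n_patients = 9896, seed = 11)
  coh <- generate_cohort(cfg)
  expect_s3_class(coh, "rd_cohort")
  expect_equal(cohort_size(coh), 9896)
  expect_false(anyDuplicated(coh$records$id) > 0)

  # binomial tolerance around the configured 771/9896 tail mass
  target <- 771 / 9896
  tol <- 3 * sqrt(target * (1 - target) / 9896)
  expect_lt(abs(mean(coh$records$max_score >= 65) - target), tol)

  # determinism from the master seed
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$records, coh2$records)

  # scores bounded and on the resolution grid
  x <- coh$records$max_score
  expect_true(all(x >= 0 & x <= 100))
  expect_true(all(abs(x / 0.1 - round(x / 0.1)) < 1e-8))
  expect_true(all(coh$records$elixhauser >= -19 &
                    coh$records$elixhauser <= 89))
})

test_that("stream splitting isolates components: covariate model does not perturb scores", {
  cfg1 <- cohort_config(n_patients = 500, seed = 4)
  cm <- cfg1$covariate_model
  cm$age$sd <- 20
  cfg2 <- cohort_config(n_patients = 500, seed = 4, covariate_model = cm)
  c1 <- generate_cohort(cfg1); c2 <- generate_cohort(cfg2)
  expect_identical(c1$records$max_score, c2$records$max_score)
  expect_identical(c1$records$rrt, c2$records$rrt)
  expect_false(identical(c1$records$age, c2$records$age))
})

test_that("invalid outcome probabilities are rejected naming the offending score", {
  expect_error(
    cohort_config(tau = -0.9),
    "invalid outcome probability at attainable score 65.0")
})

test_that("null generator (tau = 0) is continuous at the threshold", {
  # brute-force bin-rate comparison just below vs just above the cutoff
  coh <- generate_cohort(cohort_config(n_patients = 50000, tau = 0, seed = 9))
  df <- coh$records
  y <- composite_outcome(df, "primary")
  below <- df$max_score >= 64.5 & df$max_score < 65
  above <- df$max_score >= 65 & df$max_score < 65.5
  diff <- mean(y[above]) - mean(y[below])
  se <- sqrt(var(y[below]) / sum(below) + var(y[above]) / sum(above))
  expect_lt(abs(diff), 3 * se)
})

test_that("null smoothness: large-sample RD estimate within 3 SEs of 0 over seeds", {
  for (s in 1:3) {
    coh <- generate_cohort(cohort_config(n_patients = 20000, tau = 0,
                                         seed = 100 + s))
    fit <- rd_estimate(coh, "primary")
    expect_lt(abs(fit$estimate), 3 * fit$se)
  }
})

test_that("contamination keeps assignment sharp but removes the effect for a fraction", {
  coh <- generate_cohort(cohort_config(n_patients = 20000,
                                       contamination_rate = 0.25, seed = 8))
  df <- coh$records
  above <- df$max_score >= 65
  expect_true(all(df$treated[!above] == 0))
  expect_true(all(df$contaminated[!above] == 0))
  expect_equal(df$treated[above], 1L - df$contaminated[above])
  expect_lt(abs(mean(df$contaminated[above]) - 0.25), 0.03)
})

test_that("inject_manipulation bookkeeping: identity, exhaustion, conservation", {
  coh <- generate_cohort(cohort_config(n_patients = 10000, seed = 13))
  expect_identical(inject_manipulation(coh, 0, 1), coh)

  emptied <- inject_manipulation(coh, 1, 1, seed = 2)
  x <- emptied$records$max_score
  expect_equal(sum(x >= 64 & x < 65), 0)
  expect_equal(cohort_size(emptied), cohort_size(coh))

  x0 <- coh$records$max_score
  n_src <- sum(x0 >= 64 & x0 < 65)
  shifted <- inject_manipulation(coh, 0.3, 1, seed = 2)
  x1 <- shifted$records$max_score
  removed <- n_src - sum(x1 >= 64 & x1 < 65)
  expect_equal(removed, round(0.3 * n_src))
  gained <- sum(x1 >= 65 & x1 < 66) - sum(x0 >= 65 & x0 < 66)
  expect_equal(gained, removed)
  # everything outside the two windows untouched
  out <- x0 < 64 | x0 >= 66
  expect_identical(x1[out], x0[out])
})

test_that("inject_manipulation warns and returns unchanged on an empty source window", {
  coh <- hand_cohort(x = c(10, 20, 80), y = c(0, 0, 1))
  expect_warning(out <- inject_manipulation(coh, 0.5, 1), "source window")
  expect_identical(out$records, coh$records)
})

test_that("censored_max takes the maximum strictly before the event step", {
  path <- c(40, 55, 70, 80)
  expect_equal(censored_max(path, 4), 70)   # event at 0-based step 3
  expect_equal(censored_max(path, NA), 80)  # no event
  expect_equal(censored_max(path, 1), 40)   # first step always observed
})

test_that("trajectory maxima match generate_cohort's score distribution under zero hazard", {
  cfg <- cohort_config(n_patients = 4000, seed = 21)
  traj <- simulate_trajectory_max(cfg, n_steps = 40,
                                  hazard = list(intercept = -Inf, slope = 0))
  expect_true(all(traj$records[c("rrt", "icu_transfer", "arrest",
                                 "death")] == 0))
  # an independent draw from the same configured distribution
  direct <- generate_cohort(cohort_config(n_patients = 4000, seed = 22))
  ks <- suppressWarnings(
    ks.test(traj$records$max_score, direct$records$max_score))
  expect_lt(unname(ks$statistic), 0.05)

  # with a positive hazard, censoring can only pull maxima down
  cens <- simulate_trajectory_max(cfg, n_steps = 40,
                                  hazard = list(intercept = -4, slope = 0.03))
  expect_lte(mean(cens$records$max_score), mean(traj$records$max_score))
  expect_gt(sum(rowSums(cens$records[c("rrt", "icu_transfer", "arrest",
                                       "death")]) > 0), 0)
})
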