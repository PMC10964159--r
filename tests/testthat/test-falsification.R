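# falsification suite: covariate balance, placebo, assignment, aggregation

test_that("covariate_balance tests exactly the three design covariates by default", {
  coh <- generate_cohort(small_config(n = 6000, seed = 61))
  bal <- covariate_balance(coh)
  expect_named(bal, c("age", "elixhauser", "days_to_max"))
  for (nm in names(bal)) {
    expect_s3_class(bal[[nm]], "rd_fit")
    expect_false(bal[[nm]]$units == "percentage points")
  }
  expect_error(covariate_balance(coh, c("age", "bmi")), "bmi")
})

test_that("covariate balance flags a constructed 5-unit jump", {
  coh <- generate_cohort(cohort_config(n_patients = 10000, seed = 63))
  df <- coh$records
  df$age <- df$age + 5 * (df$max_score >= 65)
  coh$records <- df
  bal <- covariate_balance(coh)
  expect_true("age" %in% attr(bal, "flagged"))
})

test_that("missing covariates are excluded only from that covariate's fit", {
  coh <- generate_cohort(cohort_config(n_patients = 6000, seed = 65,
                                       missing_covariate_rate = 0.1))
  bal <- covariate_balance(coh, settings = list(h = 10))
  n_days <- bal$days_to_max$n_left + bal$days_to_max$n_right
  n_age <- bal$age$n_left + bal$age$n_right
  expect_gt(n_days, n_age)  # days_to_max has no missingness
})

test_that("placebo_test is the standard estimator and is calibrated on null cohorts", {
  coh <- generate_cohort(cohort_config(n_patients = 8000, tau = 0, seed = 67,
                                       period = "pre_implementation"))
  fit <- placebo_test(coh, settings = list(h = 7))
  direct <- rd_estimate(coh, "primary", spec = kernel_spec("triangular", 7))
  expect_identical(fit$estimate, direct$estimate)
  expect_identical(fit$se, direct$se)
})

test_that("a real effect mislabeled as placebo is detected far above the null rate", {
  # sanity inversion: with the true -10.4pp jump present, the placebo check
  # fires at its full power (~0.5 in this world at n = 10,000: |tau|/se is
  # close to 2), an order of magnitude above the 5% null rejection rate
  hits <- logical(40)
  for (s in seq_along(hits)) {
    coh <- generate_cohort(cohort_config(n_patients = 10000, tau = -0.104,
                                         seed = 700 + s))
    hits[s] <- placebo_test(coh)$p_value < 0.05
  }
  expect_gte(mean(hits), 8 * 0.05)
})

test_that("assignment discontinuity is 1 for sharp cohorts and 1 - f under contamination", {
  sharp <- generate_cohort(cohort_config(n_patients = 8000, seed = 71))
  ad <- assignment_discontinuity(sharp)
  expect_equal(ad$jump$estimate, 1, tolerance = 1e-9)
  below <- ad$bins$center < 65 & ad$bins$count > 0
  above <- ad$bins$center > 65 & ad$bins$count > 0
  expect_true(all(ad$bins$prop_treated[below] == 0))
  expect_true(all(ad$bins$prop_treated[above] == 1))
  expect_equal(sum(ad$bins$count), 8000)

  cont <- generate_cohort(cohort_config(n_patients = 20000,
                                        contamination_rate = 0.3, seed = 73))
  ad2 <- assignment_discontinuity(cont)
  expect_lt(abs(ad2$jump$estimate - 0.7), 0.08)
})

test_that("run_falsification aggregates all checks with re-derivable verdicts", {
  coh <- generate_cohort(cohort_config(n_patients = 8000, seed = 75))
  plc <- generate_cohort(cohort_config(n_patients = 8000, tau = 0, seed = 76,
                                       period = "pre_implementation"))
  rep <- run_falsification(coh, plc)
  expect_s3_class(rep, "falsification_report")
  expect_setequal(rep$verdicts$check,
                  c("density", "covariate_balance", "placebo", "assignment"))
  # verdicts are pure functions of the stored fits
  expect_equal(rep$verdicts$pass[rep$verdicts$check == "density"],
               rep$density_result$p_value >= rep$alpha)
  expect_equal(rep$verdicts$pass[rep$verdicts$check == "placebo"],
               rep$placebo_fit$p_value >= rep$alpha)
  expect_equal(rep$verdicts$pass[rep$verdicts$check == "covariate_balance"],
               length(attr(rep$covariate_fits, "flagged")) == 0)
  # determinism: same inputs reproduce identical numbers
  rep2 <- run_falsification(coh, plc)
  expect_equal(rep$density_result$theta, rep2$density_result$theta)
  expect_equal(rep$placebo_fit$estimate, rep2$placebo_fit$estimate)
})

test_that("manipulation flags the density check without flipping the others", {
  coh <- generate_cohort(cohort_config(n_patients = 10000, seed = 81))
  plc <- generate_cohort(cohort_config(n_patients = 10000, tau = 0,
                                       seed = 82,
                                       period = "pre_implementation"))
  clean <- run_falsification(coh, plc)
  shifted <- inject_manipulation(coh, 0.5, 1, seed = 4)
  dirty <- run_falsification(shifted, plc)
  v <- function(r, chk) r$verdicts$pass[r$verdicts$check == chk]
  expect_true(v(clean, "density"))
  expect_false(v(dirty, "density"))
  for (chk in c("covariate_balance", "placebo", "assignment")) {
    expect_equal(v(dirty, chk), v(clean, chk))
  }
  # the placebo arm is untouched, so its numbers are bitwise identical
  expect_identical(dirty$placebo_fit$estimate, clean$placebo_fit$estimate)
})
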