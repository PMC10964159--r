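#' Configuration for the synthetic hospitalization cohort generator
#'
#' Describes a stylized ward population monitored by a 0-100 deterioration
#' index. Each hospitalization contributes one running-variable value (the
#' maximum score, censored at the first event) and binary event flags.
#' Patients at or above `threshold` trigger the alert; the alert lowers the
#' probability of the primary composite outcome by `tau` (a probability
#' difference, negative for a protective effect), except for a
#' `contamination_rate` fraction of above-threshold patients (silent alerts,
#' comfort-care orders) who carry the assignment but receive no effect.
#'
#' Defaults state the world the downstream analysis assumes: n = 9896
#' hospitalizations, 771/9896 (7.8\%) at or above a threshold of 65.0,
#' a true jump of -0.104 in the primary composite at the threshold, smooth
#' logistic outcome curves, and covariates (age, Elixhauser comorbidity
#' index, days from admission to maximum score) smooth in the score.
#'
#' @param n_patients number of hospitalizations to generate
#' @param threshold alert threshold on the score scale (default 65.0)
#' @param tau true jump in primary-outcome probability at the threshold for
#'   treated patients (default -0.104)
#' @param baseline_curve list(intercept, slope): primary-outcome probability
#'   below the threshold is `plogis(intercept + slope * (score - threshold))`
#' @param score_dist list(shape1, shape2, frac_above): maximum score is
#'   `100 * Beta(shape1, shape2)` rounded to `score_resolution`. If `shape2`
#'   is NULL it is solved so that `P(score >= threshold) = frac_above`
#'   (default 771/9896).
#' @param covariate_model named list; each covariate has
#'   list(base, slope, sd, lower, upper, digits): mean `base + slope * score`,
#'   Gaussian noise `sd`, clamped to `[lower, upper]`, rounded to `digits`
#' @param mortality_curve list(intercept, slope, jump): inpatient death
#'   probability, same parameterization as `baseline_curve`; `jump` (default
#'   0) is an optional discontinuity for treated patients
#' @param contamination_rate fraction of above-threshold patients who carry
#'   assignment but receive no treatment effect (default 0)
#' @param manipulation_shift fraction of mass relocated from just below to
#'   just above the threshold, for density-test power studies (default 0)
#' @param manipulation_window width (score units) of the relocation window
#' @param missing_covariate_rate fraction of records with age and comorbidity
#'   index set missing (default 0)
#' @param score_resolution rounding grain of the recorded score (default 0.1)
#' @param period cohort period label, `"active"` or `"pre_implementation"`
#' @param unit unit label attached to all records
#' @param seed master integer seed; sub-streams are split per component via
#'   [sub_seed()] so the draws of one component do not perturb another
#'
#' @return an object of class `cohort_config`
#' @seealso [generate_cohort()], [simulate_trajectory_max()]
#' @export
cohort_config <- function(n_patients = 9896,
                          threshold = 65,
                          tau = -0.104,
                          baseline_curve = list(intercept = stats::qlogis(0.35),
                                                slope = 0.04),
                          score_dist = list(shape1 = 1.6, shape2 = NULL,
                                            frac_above = 771 / 9896),
                          covariate_model = default_covariate_model(),
                          mortality_curve = list(intercept = stats::qlogis(0.10),
                                                 slope = 0.05, jump = 0),
                          contamination_rate = 0,
                          manipulation_shift = 0,
                          manipulation_window = 1,
                          missing_covariate_rate = 0,
                          score_resolution = 0.1,
                          period = "active",
                          unit = "unit_01",
                          seed = 1L) {
  stopifnot(n_patients >= 1, threshold > 0, threshold < 100,
            score_resolution > 0,
            contamination_rate >= 0, contamination_rate <= 1,
            manipulation_shift >= 0, manipulation_shift <= 1,
            manipulation_window > 0,
            missing_covariate_rate >= 0, missing_covariate_rate <= 1)
  if (is.null(score_dist$shape2)) {
    score_dist$shape2 <- solve_beta_shape2(score_dist$shape1,
                                           threshold / 100,
                                           score_dist$frac_above)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients), threshold = threshold, tau = tau,
    baseline_curve = baseline_curve, score_dist = score_dist,
    covariate_model = covariate_model, mortality_curve = mortality_curve,
    contamination_rate = contamination_rate,
    manipulation_shift = manipulation_shift,
    manipulation_window = manipulation_window,
    missing_covariate_rate = missing_covariate_rate,
    score_resolution = score_resolution,
    period = period, unit = unit, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

default_covariate_model <- function() {
  list(
    age         = list(base = 60, slope = 0.25, sd = 12,
                       lower = 18, upper = 110, digits = 1),
    elixhauser  = list(base = -2, slope = 0.18, sd = 10,
                       lower = -19, upper = 89, digits = 0),
    days_to_max = list(base = 1, slope = 0.03, sd = 1.5,
                       lower = 0, upper = 60, digits = 2)
  )
}

# shape2 such that P(Beta(shape1, shape2) >= q) = frac
solve_beta_shape2 <- function(shape1, q, frac) {
  stopifnot(shape1 > 0, frac > 0, frac < 1)
  f <- function(b) 1 - stats::pbeta(q, shape1, b) - frac
  stats::uniroot(f, c(1e-3, 1e3), tol = 1e-10)$root
}

# every attainable (rounded) score must map to a valid probability
validate_cohort_config <- function(cfg) {
  grid <- seq(0, 100, by = cfg$score_resolution)
  for (treated in c(FALSE, TRUE)) {
    p <- outcome_probability(cfg, grid, treated = treated)
    pd <- death_probability(cfg, grid, treated = treated)
    bad <- grid[p < 0 | p > 1 | pd < 0 | pd > 1]
    if (length(bad)) {
      stop(sprintf(
        "invalid outcome probability at attainable score %.1f (treated = %s)",
        bad[1], treated), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' @rdname cohort_config
#' @param config a `cohort_config`
#' @param score numeric score values
#' @param treated logical: apply the treatment-effect jump above threshold?
#' @export
outcome_probability <- function(config, score, treated = TRUE) {
  p <- stats::plogis(config$baseline_curve$intercept +
                       config$baseline_curve$slope * (score - config$threshold))
  p + config$tau * as.numeric(treated & score >= config$threshold)
}

death_probability <- function(config, score, treated = TRUE) {
  p <- stats::plogis(config$mortality_curve$intercept +
                       config$mortality_curve$slope * (score - config$threshold))
  jump <- config$mortality_curve$jump %||% 0
  p + jump * as.numeric(treated & score >= config$threshold)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  n_patients: %d   threshold: %.1f   tau: %+.3f\n",
              x$n_patients, x$threshold, x$tau))
  cat(sprintf("  score ~ 100 * Beta(%.3f, %.3f); P(>= threshold) = %.4f\n",
              x$score_dist$shape1, x$score_dist$shape2,
              1 - stats::pbeta(x$threshold / 100, x$score_dist$shape1,
                               x$score_dist$shape2)))
  cat(sprintf("  contamination: %.2f   manipulation_shift: %.2f   seed: %d\n",
              x$contamination_rate, x$manipulation_shift, x$seed))
  invisible(x)
}
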