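# synthetic cohort generation

#' Generate a synthetic hospitalization cohort
#'
#' Draws `n_patients` records under the potential-outcome model
#' `P(primary event) = baseline_curve(score) + tau * 1{score >= threshold} *
#' 1{not contaminated}`: a smooth logistic risk curve plus a known jump at
#' the alert threshold. The maximum deterioration-index score is drawn from
#' a right-skewed scaled Beta distribution and rounded to
#' `score_resolution`; covariates are smooth functions of the score plus
#' Gaussian noise; inpatient death follows its own smooth curve (no jump
#' unless configured), so the secondary composite shows an attenuated
#' effect. Fully reproducible from `config$seed`; each component draws from
#' its own named sub-stream.
#'
#' @param config a [cohort_config()]
#' @return an `rd_cohort`
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 500, seed = 7))
#' mean(coh$records$max_score >= 65)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  n <- config$n_patients
  c0 <- config$threshold
  res <- config$score_resolution

  set.seed(sub_seed(config$seed, "scores"))
  x <- draw_scores(config, n)

  # optional bunching for density-test power studies, applied pre-assignment
  if (config$manipulation_shift > 0) {
    set.seed(sub_seed(config$seed, "manipulation"))
    x <- relocate_scores(x, c0, config$manipulation_shift,
                         config$manipulation_window, res)
  }

  assigned <- as.integer(x >= c0)
  set.seed(sub_seed(config$seed, "contamination"))
  contaminated <- as.integer(assigned == 1 &
                               stats::runif(n) < config$contamination_rate)
  effective <- assigned == 1 & contaminated == 0

  set.seed(sub_seed(config$seed, "outcomes"))
  p_primary <- stats::plogis(config$baseline_curve$intercept +
                               config$baseline_curve$slope * (x - c0)) +
    config$tau * as.numeric(effective)
  y_primary <- stats::rbinom(n, 1L, p_primary)

  set.seed(sub_seed(config$seed, "components"))
  flags <- split_composite(y_primary)

  set.seed(sub_seed(config$seed, "death"))
  p_death <- stats::plogis(config$mortality_curve$intercept +
                             config$mortality_curve$slope * (x - c0)) +
    (config$mortality_curve$jump %||% 0) * as.numeric(effective)
  death <- stats::rbinom(n, 1L, p_death)

  covs <- draw_covariates(config, x)

  if (config$missing_covariate_rate > 0) {
    set.seed(sub_seed(config$seed, "missingness"))
    miss <- stats::runif(n) < config$missing_covariate_rate
    covs$age[miss] <- NA_real_
    covs$elixhauser[miss] <- NA_real_
  }

  df <- data.frame(
    id = sprintf("pt%07d", seq_len(n)),
    max_score = x,
    treated = as.integer(effective),
    rrt = flags$rrt, icu_transfer = flags$icu_transfer, arrest = flags$arrest,
    death = death,
    age = covs$age, elixhauser = covs$elixhauser,
    days_to_max = covs$days_to_max,
    period = config$period, unit = config$unit,
    contaminated = contaminated,
    stringsAsFactors = FALSE
  )
  cohort <- new_cohort(df, c0, provenance = list(config = config))
  validate_cohort(cohort, source = "generate_cohort")
  cohort
}

draw_scores <- function(config, n) {
  x <- 100 * stats::rbeta(n, config$score_dist$shape1, config$score_dist$shape2)
  clamp(round_to(x, config$score_resolution), 0, 100)
}

# decompose the primary composite into rrt / icu transfer / arrest flags;
# conditional on an event, ICU transfer is the most common escalation and
# cardiopulmonary arrest the rarest; at least one flag is guaranteed
split_composite <- function(y_primary) {
  n <- length(y_primary)
  rrt <- as.integer(y_primary == 1L & stats::runif(n) < 0.55)
  icu <- as.integer(y_primary == 1L & stats::runif(n) < 0.60)
  arrest <- as.integer(y_primary == 1L & stats::runif(n) < 0.04)
  none <- y_primary == 1L & rrt == 0L & icu == 0L & arrest == 0L
  icu[none] <- 1L
  list(rrt = rrt, icu_transfer = icu, arrest = arrest)
}

draw_covariates <- function(config, x) {
  out <- list()
  for (nm in names(config$covariate_model)) {
    cm <- config$covariate_model[[nm]]
    set.seed(sub_seed(config$seed, paste0("cov_", nm)))
    v <- cm$base + cm$slope * x + stats::rnorm(length(x), 0, cm$sd)
    out[[nm]] <- round(clamp(v, cm$lower, cm$upper), cm$digits %||% 2)
  }
  out
}

#' Simulate per-patient score trajectories and record the censored maximum
#'
#' Each patient follows a bounded severity excursion on \[0, 100\]: a latent
#' peak severity is drawn from the configured score distribution and the
#' trajectory is the peak minus the absolute excursion of a Gaussian random
#' walk (so the walk attains its peak exactly once and stays in bounds). At
#' every step an event fires with probability increasing in the current
#' score; the recorded running variable is the maximum score over steps
#' strictly before the event step (the first step is always observed), which
#' is how real deterioration scores are censored at the time of an event.
#' With zero hazard the recorded maximum equals the maximum over all steps,
#' so the score distribution matches [generate_cohort()] exactly.
#'
#' @param config a [cohort_config()]
#' @param n_steps number of 15-minute scoring steps per hospitalization
#' @param hazard list(intercept, slope): per-step event probability is
#'   `plogis(intercept + slope * score)`; `list(intercept = -Inf)` disables
#'   events
#' @param step_sd standard deviation of the walk increments (score units)
#' @return an `rd_cohort`; event flags are set from the event type at
#'   occurrence (no event: all flags 0)
#' @export
simulate_trajectory_max <- function(config, n_steps,
                                    hazard = list(intercept = -8, slope = 0.05),
                                    step_sd = 3) {
  stopifnot(inherits(config, "cohort_config"), n_steps >= 1)
  n <- config$n_patients
  c0 <- config$threshold

  set.seed(sub_seed(config$seed, "scores"))
  peak <- draw_scores(config, n)

  set.seed(sub_seed(config$seed, "trajectory"))
  x <- numeric(n)
  event_type <- character(n)
  types <- c("rrt", "icu_transfer", "arrest", "death")
  type_prob <- c(0.35, 0.50, 0.05, 0.10)
  for (i in seq_len(n)) {
    w <- cumsum(stats::rnorm(n_steps, 0, step_sd))
    path <- clamp(peak[i] - (w - min(w)), 0, 100)
    p_event <- stats::plogis(hazard$intercept + (hazard$slope %||% 0) * path)
    fired <- which(stats::runif(n_steps) < p_event)
    ev <- if (length(fired)) fired[1] else NA_integer_
    x[i] <- censored_max(path, ev)
    event_type[i] <- if (is.na(ev)) "" else sample(types, 1, prob = type_prob)
  }
  x <- clamp(round_to(x, config$score_resolution), 0, 100)

  covs <- draw_covariates(config, x)
  df <- data.frame(
    id = sprintf("pt%07d", seq_len(n)),
    max_score = x,
    treated = as.integer(x >= c0),
    rrt = as.integer(event_type == "rrt"),
    icu_transfer = as.integer(event_type == "icu_transfer"),
    arrest = as.integer(event_type == "arrest"),
    death = as.integer(event_type == "death"),
    age = covs$age, elixhauser = covs$elixhauser,
    days_to_max = covs$days_to_max,
    period = config$period, unit = config$unit,
    contaminated = 0L,
    stringsAsFactors = FALSE
  )
  cohort <- new_cohort(df, c0,
                       provenance = list(config = config, n_steps = n_steps))
  validate_cohort(cohort, source = "simulate_trajectory_max")
  cohort
}

#' Maximum of a trajectory censored at an event step
#'
#' Returns the maximum over steps strictly before `event_step` (1-based).
#' `event_step = NA` means no event (maximum over all steps); an event at
#' the very first step returns that step's score, since at least one score
#' is always observed.
#'
#' @param path numeric trajectory
#' @param event_step 1-based index of the event step, or NA
#' @return the censored maximum
#' @export
censored_max <- function(path, event_step) {
  if (is.na(event_step)) return(max(path))
  stopifnot(event_step >= 1, event_step <= length(path))
  if (event_step == 1L) path[1] else max(path[seq_len(event_step - 1L)])
}

#' Relocate score mass across the threshold (density-test power tool)
#'
#' Moves `shift_fraction` of the records with score in
#' `[threshold - window, threshold)` to uniformly drawn grid scores in
#' `[threshold, threshold + window)`. The `treated` flag is recomputed from
#' the new scores (assignment follows the realized score); everything else
#' is left unchanged — this exists to exercise the power of the McCrary
#' density test, not to model a coherent manipulated cohort.
#'
#' @param cohort an `rd_cohort`
#' @param shift_fraction fraction of source-window records to relocate
#' @param window window width on the score scale
#' @param seed optional seed for the relocation draws
#' @return a modified `rd_cohort` with the same number of records; only the
#'   scores of the relocated records and the assignment-derived `treated`
#'   flag change
#' @export
inject_manipulation <- function(cohort, shift_fraction, window, seed = NULL) {
  stopifnot(inherits(cohort, "rd_cohort"),
            shift_fraction >= 0, shift_fraction <= 1, window > 0)
  if (shift_fraction == 0) return(cohort)
  if (!is.null(seed)) set.seed(seed)
  res <- cohort$provenance$config$score_resolution %||% 0.1
  cohort$records$max_score <- relocate_scores(
    cohort$records$max_score, cohort$threshold, shift_fraction, window, res)
  # assignment follows the realized score: records pushed across the cutoff
  # trigger the alert (manipulation happens before assignment)
  if (all(c("treated", "contaminated") %in% names(cohort$records))) {
    cohort$records$treated <- as.integer(
      cohort$records$max_score >= cohort$threshold &
        cohort$records$contaminated == 0)
  }
  cohort
}

relocate_scores <- function(x, c0, shift_fraction, window, res) {
  src <- which(x >= c0 - window & x < c0)
  if (!length(src)) {
    warning("no records in the source window [threshold - window, threshold); ",
            "cohort returned unchanged")
    return(x)
  }
  n_move <- round(shift_fraction * length(src))
  if (n_move == 0) return(x)
  move <- if (n_move == length(src)) src else sample(src, n_move)
  grid <- seq(c0, c0 + window - res, by = res)
  x[move] <- sample(grid, n_move, replace = TRUE)
  x
}
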