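# outcome definitions shared by the estimator and the pipeline

#' Composite outcomes of a hospitalization
#'
#' The primary composite is an escalation of care: rapid response team
#' activation, ICU transfer, or cardiopulmonary arrest. The secondary
#' composite adds inpatient death.
#'
#' @param record a `Hospitalization` row (or any data frame with the event
#'   flag columns `rrt`, `icu_transfer`, `arrest`, and for the secondary
#'   composite `death`)
#' @param which `"primary"` or `"secondary"`
#' @return integer 0/1 vector
#' @export
composite_outcome <- function(record, which = c("primary", "secondary")) {
  which <- match.arg(which)
  need <- c("rrt", "icu_transfer", "arrest",
            if (which == "secondary") "death")
  missing_cols <- setdiff(need, names(record))
  if (length(missing_cols)) {
    stop_stage("outcome", "missing event flag column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  y <- as.integer(record$rrt | record$icu_transfer | record$arrest)
  if (which == "secondary") y <- as.integer(y | record$death)
  y
}

# outcome labels understood by the estimator; composites are derived,
# everything else must be a column of the cohort table
outcome_vector <- function(cohort, outcome_label) {
  df <- if (inherits(cohort, "rd_cohort")) cohort$records else cohort
  switch(outcome_label,
    primary = composite_outcome(df, "primary"),
    secondary = composite_outcome(df, "secondary"),
    rrt_or_arrest = {
      missing_cols <- setdiff(c("rrt", "arrest"), names(df))
      if (length(missing_cols)) {
        stop_stage("outcome", "missing event flag column(s): %s",
                   paste(missing_cols, collapse = ", "))
      }
      as.integer(df$rrt | df$arrest)
    },
    {
      if (!outcome_label %in% names(df)) {
        stop_stage("outcome", "unknown outcome label '%s'", outcome_label)
      }
      v <- df[[outcome_label]]
      if (!is.numeric(v)) {
        stop_stage("outcome", "outcome '%s' is not numeric", outcome_label)
      }
      v
    })
}

# binary outcomes are reported in percentage points, continuous covariates
# in native units (years, index points, days)
is_binary_outcome <- function(outcome_label) {
  outcome_label %in% c("primary", "secondary", "rrt", "icu_transfer",
                       "arrest", "death", "rrt_or_arrest", "treated")
}

outcome_units <- function(outcome_label) {
  if (is_binary_outcome(outcome_label)) "percentage points"
  else switch(outcome_label,
              age = "years", elixhauser = "index points",
              days_to_max = "days", "native units")
}
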