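# falsification suite: covariate balance, placebo cohorts, assignment
# discontinuity, and the aggregated report

#' Covariate balance at the threshold
#'
#' Runs the RD estimator with each pre-treatment covariate as the outcome.
#' Under a valid design, covariates are smooth through the cutoff, so every
#' discontinuity estimate should be indistinguishable from zero. Records
#' missing a covariate are excluded from that covariate's fit only. Each
#' covariate gets its own MSE-optimal bandwidth unless `settings$h`
#' overrides it.
#'
#' @param cohort an `rd_cohort`
#' @param covariate_labels covariates to test (default: age, Elixhauser
#'   comorbidity index, days from admission to maximum score)
#' @param c cutoff (default: the cohort threshold)
#' @param settings optional list: `h`, `kernel`, `order`, `alpha`, `vce`
#' @return an object of class `covariate_balance`: named list of `rd_fit`s
#'   with a `flagged` attribute (covariates whose CI excludes 0)
#' @export
covariate_balance <- function(cohort,
                              covariate_labels = c("age", "elixhauser",
                                                   "days_to_max"),
                              c = NULL, settings = list()) {
  c <- c %||% cohort$threshold
  df <- cohort$records
  kernel <- settings$kernel %||% "triangular"
  order <- settings$order %||% 1L
  alpha <- settings$alpha %||% 0.05
  vce <- settings$vce %||% "hc1"
  fits <- list()
  for (cov in covariate_labels) {
    if (!cov %in% names(df)) {
      stop_stage("balance", "covariate '%s' not present in the cohort", cov)
    }
    if (all(is.na(df[[cov]]))) {
      stop_stage("balance", "covariate '%s' is entirely missing", cov)
    }
    sub <- cohort
    sub$records <- df[!is.na(df[[cov]]), , drop = FALSE]
    h <- settings$h %||% cct_bandwidth(sub, cov, c, kernel, order)
    fits[[cov]] <- rd_estimate(sub, cov, c, kernel_spec(kernel, h),
                               order, alpha, vce)
  }
  flagged <- names(fits)[vapply(fits, function(f) {
    f$ci_low > 0 || f$ci_high < 0
  }, logical(1))]
  structure(fits, flagged = flagged, class = "covariate_balance")
}

#' @export
print.covariate_balance <- function(x, ...) {
  cat("<covariate_balance> RD estimates on pre-treatment covariates\n")
  for (nm in names(x)) {
    f <- x[[nm]]
    cat(sprintf("  %-12s %+7.2f %s (CI %+.2f to %+.2f), h = %.2f, p = %s\n",
                nm, f$estimate, f$units, f$ci_low, f$ci_high,
                f$bandwidth, format_pvalue(f$p_value)))
  }
  fl <- attr(x, "flagged")
  cat(if (length(fl)) paste("  FLAGGED:", paste(fl, collapse = ", "), "\n")
      else "  all covariate CIs cover 0\n")
  invisible(x)
}

#' Placebo RD analysis on an unexposed cohort
#'
#' The same RD estimator applied to a cohort in which the score was
#' computed but no alert was shown (a pre-implementation period or
#' silent-scoring units). A significant discontinuity here flags a spurious
#' association between the score and the outcome at the threshold.
#'
#' @param placebo_cohort an `rd_cohort`, ideally with period label
#'   `pre_implementation`
#' @param c cutoff
#' @param settings optional list: `h` (default: MSE-optimal), `kernel`,
#'   `order`, `alpha`, `vce`, `outcome_label` (default `"primary"`)
#' @return an `rd_fit`
#' @export
placebo_test <- function(placebo_cohort, c = NULL, settings = list()) {
  c <- c %||% placebo_cohort$threshold
  outcome <- settings$outcome_label %||% "primary"
  kernel <- settings$kernel %||% "triangular"
  order <- settings$order %||% 1L
  h <- settings$h %||% cct_bandwidth(placebo_cohort, outcome, c, kernel, order)
  rd_estimate(placebo_cohort, outcome, c, kernel_spec(kernel, h), order,
              settings$alpha %||% 0.05, settings$vce %||% "hc1")
}

#' Discontinuity in treatment assignment at the threshold
#'
#' Verifies the sharp-design premise: the fraction of patients who actually
#' received the intervention should jump from 0 to 1 at the cutoff. Returns
#' per-bin treated proportions and a local linear estimate of the jump.
#' Under contamination (silent alerts, comfort care) the jump falls below 1
#' by the contamination rate.
#'
#' @param cohort an `rd_cohort` with a `treated` column
#' @param c cutoff
#' @param bin_width bin width for the proportion plot (default 1)
#' @param h bandwidth for the local linear jump estimate (default 7)
#' @return list with `bins` (center, count, prop_treated) and `jump`
#'   (an `rd_fit` on the treated indicator)
#' @export
assignment_discontinuity <- function(cohort, c = NULL, bin_width = 1, h = 7) {
  c <- c %||% cohort$threshold
  df <- cohort$records
  stopifnot("treated" %in% names(df), bin_width > 0)
  l <- floor((df$max_score - c) / bin_width)
  rng <- seq(min(l), max(l))
  idx <- match(l, rng)
  count <- tabulate(idx, nbins = length(rng))
  treated_n <- vapply(seq_along(rng),
                      function(j) sum(df$treated[idx == j]), numeric(1))
  bins <- data.frame(center = c + (rng + 0.5) * bin_width,
                     count = count,
                     prop_treated = ifelse(count > 0, treated_n / count, NA))
  jump <- rd_estimate(cohort, "treated", c, kernel_spec("triangular", h), 1L)
  list(bins = bins, jump = jump)
}

#' Run the full falsification suite
#'
#' Executes the validity checks of the RD design with shared settings: the
#' McCrary density test (no sorting at the cutoff), covariate balance
#' (confounders smooth through the cutoff), the placebo analysis (no effect
#' where no alert was shown), and the assignment discontinuity (treatment
#' delivery is sharp). Each check's verdict is a pure function of its
#' stored fit, re-derivable from the report. Individual check failures are
#' recorded per check, not fatal to the report. No multiplicity adjustment
#' is applied across checks — each is reported at its own `alpha`.
#'
#' @param cohort the exposed (active-period) `rd_cohort`
#' @param placebo_cohort an unexposed `rd_cohort`
#' @param config optional list: `alpha` (default 0.05), `covariates`,
#'   `bin_width`, `h` (bandwidth override for all RD fits),
#'   `sharp_jump_min` (assignment verdict threshold, default 0.95)
#' @return an object of class `falsification_report`
#' @export
run_falsification <- function(cohort, placebo_cohort, config = list()) {
  alpha <- config$alpha %||% 0.05
  sharp_min <- config$sharp_jump_min %||% 0.95
  c <- cohort$threshold
  run_check <- function(expr) tryCatch(expr, error = function(e) e)

  density_result <- run_check(mccrary_test(cohort, c))
  balance <- run_check(covariate_balance(
    cohort, config$covariates %||% c("age", "elixhauser", "days_to_max"),
    c, settings = list(alpha = alpha, h = config$h)))
  placebo <- run_check(placebo_test(placebo_cohort, placebo_cohort$threshold,
                                    settings = list(alpha = alpha,
                                                    h = config$h)))
  assignment <- run_check(assignment_discontinuity(
    cohort, c, config$bin_width %||% 1, h = config$h %||% 7))

  verdict <- function(name, obj, pass, rule) {
    if (inherits(obj, "error")) {
      data.frame(check = name, pass = NA, rule = rule,
                 note = conditionMessage(obj), stringsAsFactors = FALSE)
    } else {
      data.frame(check = name, pass = pass, rule = rule, note = "",
                 stringsAsFactors = FALSE)
    }
  }
  verdicts <- rbind(
    verdict("density", density_result,
            !inherits(density_result, "error") &&
              density_result$p_value >= alpha,
            sprintf("McCrary p >= %.2f", alpha)),
    verdict("covariate_balance", balance,
            !inherits(balance, "error") &&
              length(attr(balance, "flagged")) == 0,
            "all covariate CIs cover 0"),
    verdict("placebo", placebo,
            !inherits(placebo, "error") && placebo$p_value >= alpha,
            sprintf("placebo p >= %.2f", alpha)),
    verdict("assignment", assignment,
            !inherits(assignment, "error") &&
              assignment$jump$estimate >= sharp_min,
            sprintf("treated-fraction jump >= %.2f", sharp_min))
  )
  structure(list(density_result = density_result, covariate_fits = balance,
                 placebo_fit = placebo, assignment = assignment,
                 verdicts = verdicts, alpha = alpha),
            class = "falsification_report")
}

#' @export
print.falsification_report <- function(x, ...) {
  cat("<falsification_report>\n")
  v <- x$verdicts
  for (i in seq_len(nrow(v))) {
    status <- if (is.na(v$pass[i])) "ERROR"
              else if (v$pass[i]) "pass" else "FLAG"
    cat(sprintf("  %-18s %-5s (%s)%s\n", v$check[i], status, v$rule[i],
                if (nzchar(v$note[i])) paste0(" - ", v$note[i]) else ""))
  }
  invisible(x)
}
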