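# end-to-end orchestration: results table, sweeps, falsification, figures

#' Analysis configuration
#'
#' @param threshold alert threshold (default 65.0)
#' @param manual_bandwidth the pre-specified conservative bandwidth for the
#'   primary analysis (default 7.0)
#' @param sweep_grid bandwidths for the sensitivity sweeps (default 1..15)
#' @param orders polynomial orders run for the primary outcome with the
#'   MSE-optimal bandwidth (default c(1, 2): local linear and quadratic)
#' @param alpha two-sided significance level (default 0.05)
#' @param outcomes non-primary outcomes in the results table (default:
#'   secondary composite, inpatient death, ICU transfer, RRT activation or
#'   arrest)
#' @param bin_width figure bin width (default 1.0)
#' @param kernel kernel name (default triangular)
#' @param run_sweep logical; run the bandwidth sensitivity sweeps
#' @param make_figures logical; write figure PDFs when an output directory
#'   is given
#' @param cohort an `rd_cohort`, a path to a cohort file, or a
#'   [cohort_config()] to generate from
#' @param placebo_cohort same, for the placebo check; `NULL` generates a
#'   pre-implementation cohort (tau = 0) from the main config
#' @param output_dir directory for outputs; `NULL` keeps results in memory
#' @param seed master seed used when cohorts are generated
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(threshold = 65, manual_bandwidth = 7,
                            sweep_grid = 1:15, orders = c(1L, 2L),
                            alpha = 0.05,
                            outcomes = c("secondary", "death",
                                         "icu_transfer", "rrt_or_arrest"),
                            bin_width = 1, kernel = "triangular",
                            run_sweep = TRUE, make_figures = TRUE,
                            cohort = NULL, placebo_cohort = NULL,
                            output_dir = NULL, seed = 1L) {
  stopifnot(manual_bandwidth > 0, alpha > 0, alpha < 1, bin_width > 0,
            all(sweep_grid > 0), !is.unsorted(sweep_grid, strictly = TRUE))
  structure(list(threshold = threshold, manual_bandwidth = manual_bandwidth,
                 sweep_grid = sweep_grid, orders = orders, alpha = alpha,
                 outcomes = outcomes, bin_width = bin_width, kernel = kernel,
                 run_sweep = run_sweep, make_figures = make_figures,
                 cohort = cohort, placebo_cohort = placebo_cohort,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Binned outcome rates around the threshold
#'
#' Event rate and count per score bin, with left-closed right-open bins
#' anchored so the cutoff is a bin edge (a record exactly at the cutoff
#' falls in the bin above). The count-weighted mean of the bin rates equals
#' the overall rate.
#'
#' @inheritParams score_histogram
#' @param outcome_label outcome name (see [outcome_vector()])
#' @return data frame with `center`, `count`, `rate`
#' @export
bin_outcome_rates <- function(cohort, outcome_label, bin_width = 1, c = NULL) {
  stopifnot(bin_width > 0)
  df <- if (inherits(cohort, "rd_cohort")) cohort$records else cohort
  c <- c %||% cohort$threshold
  y <- outcome_vector(cohort, outcome_label)
  keep <- !is.na(y) & !is.na(df$max_score)
  x <- df$max_score[keep]; y <- y[keep]
  l <- floor((x - c) / bin_width)
  rng <- seq(min(l), max(l))
  idx <- match(l, rng)
  count <- tabulate(idx, nbins = length(rng))
  events <- vapply(seq_along(rng), function(j) sum(y[idx == j]), numeric(1))
  data.frame(center = c + (rng + 0.5) * bin_width,
             count = count,
             rate = ifelse(count > 0, events / count, NA))
}

resolve_cohort <- function(spec, threshold, fallback_config = NULL) {
  if (inherits(spec, "rd_cohort")) return(spec)
  if (inherits(spec, "cohort_config")) return(generate_cohort(spec))
  if (is.character(spec)) return(read_cohort(spec, threshold))
  stop_stage("pipeline", "cannot resolve a cohort from an object of class %s",
             paste(class(spec), collapse = "/"))
}

#' Run the full analysis pipeline
#'
#' Reproduces the complete analysis on a given (synthetic or user-supplied)
#' cohort: for the primary composite outcome, local linear fits at the
#' manual bandwidth and at the MSE-optimal bandwidth plus a local quadratic
#' fit at its own MSE-optimal bandwidth; for every other configured outcome,
#' a local linear fit at a per-outcome MSE-optimal bandwidth; bandwidth
#' sensitivity sweeps for the primary and secondary composites; and the
#' falsification suite. All stages are computed before anything is written,
#' so partial outputs are never produced. With an `output_dir`, writes the
#' machine-readable results table, the formatted table (estimates in
#' percentage points to 1 decimal, bandwidths to 2, as clinical tables print
#' them), sweep tables, the falsification report, a run log with the
#' resolved seed and settings, and binned-rate figures with fitted lines.
#'
#' @param config an [analysis_config()]
#' @return an object of class `rd_analysis`: `results_table` (data frame),
#'   `fits` (named list of `rd_fit`), `falsification`, `sweeps`, `cohort`,
#'   `placebo_cohort`, `config`, `paths` (written files, if any)
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  c0 <- config$threshold

  cohort_spec <- config$cohort %||%
    cohort_config(threshold = c0, seed = config$seed)
  cohort <- resolve_cohort(cohort_spec, c0)
  placebo_spec <- config$placebo_cohort %||% placebo_config_from(cohort_spec, config$seed)
  placebo <- resolve_cohort(placebo_spec, c0)

  kern <- config$kernel
  fits <- list(); rows <- list()
  add_row <- function(label, source, fit) {
    key <- paste(label, source, sep = ".")
    fits[[key]] <<- fit
    rows[[key]] <<- cbind(data.frame(outcome = label,
                                     bandwidth_source = source,
                                     stringsAsFactors = FALSE),
                          as.data.frame(fit)[-1])
  }

  # primary outcome: manual h, MSE-optimal h, and quadratic at its own h
  add_row("primary", "manual",
          rd_estimate(cohort, "primary", c0,
                      kernel_spec(kern, config$manual_bandwidth), 1L,
                      config$alpha))
  h_cct <- cct_bandwidth(cohort, "primary", c0, kern, 1L)
  add_row("primary", "cct",
          rd_estimate(cohort, "primary", c0, kernel_spec(kern, h_cct), 1L,
                      config$alpha))
  if (2L %in% config$orders) {
    h_q <- cct_bandwidth(cohort, "primary", c0, kern, 2L)
    add_row("primary", "cct_quadratic",
            rd_estimate(cohort, "primary", c0, kernel_spec(kern, h_q), 2L,
                        config$alpha))
  }
  for (outc in config$outcomes) {
    h_o <- cct_bandwidth(cohort, outc, c0, kern, 1L)
    add_row(outc, "cct",
            rd_estimate(cohort, outc, c0, kernel_spec(kern, h_o), 1L,
                        config$alpha))
  }
  results_table <- do.call(rbind, rows)
  rownames(results_table) <- NULL

  sweeps <- NULL
  if (isTRUE(config$run_sweep)) {
    sweeps <- list(
      primary = bandwidth_sweep(cohort, "primary", c0, config$sweep_grid,
                                kern, 1L, config$alpha),
      secondary = bandwidth_sweep(cohort, "secondary", c0, config$sweep_grid,
                                  kern, 1L, config$alpha))
  }

  falsification <- run_falsification(cohort, placebo,
                                     config = list(alpha = config$alpha,
                                                   bin_width = config$bin_width))

  result <- structure(list(results_table = results_table, fits = fits,
                           falsification = falsification, sweeps = sweeps,
                           cohort = cohort, placebo_cohort = placebo,
                           config = config, paths = character(0)),
                      class = "rd_analysis")
  if (!is.null(config$output_dir)) {
    result$paths <- write_analysis_outputs(result, config$output_dir)
  }
  result
}

placebo_config_from <- function(cohort_spec, seed) {
  base <- if (inherits(cohort_spec, "cohort_config")) cohort_spec
          else cohort_config(seed = seed)
  base$tau <- 0
  base$period <- "pre_implementation"
  base$seed <- sub_seed(seed, "placebo")
  validate_cohort_config(base)
  base
}

#' Format the results table the way clinical journals print it
#'
#' Binary-outcome estimates and CI bounds in percentage points to 1 decimal,
#' bandwidths to 2 decimals, p-values without a leading zero. The underlying
#' machine-readable table keeps full precision.
#'
#' @param results_table the `results_table` data frame from [run_analysis()]
#' @return data frame of formatted character columns
#' @export
format_results_table <- function(results_table) {
  s <- ifelse(vapply(results_table$outcome, is_binary_outcome, logical(1)),
              100, 1)
  data.frame(
    Outcome = results_table$outcome,
    Bandwidth = sprintf("%.2f", results_table$bandwidth),
    Specification = results_table$bandwidth_source,
    Estimate = sprintf("%.1f (%.1f to %.1f)",
                       s * results_table$estimate,
                       s * results_table$ci_low,
                       s * results_table$ci_high),
    P = format_pvalue(results_table$p_value),
    stringsAsFactors = FALSE)
}

write_analysis_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- character(0)
  wr <- function(name) { p <- file.path(output_dir, name); paths <<- c(paths, p); p }

  utils::write.csv(result$results_table, wr("results_table.csv"),
                   row.names = FALSE)
  fmt <- format_results_table(result$results_table)
  writeLines(utils::capture.output(print(fmt, row.names = FALSE)),
             wr("results_table.txt"))
  if (!is.null(result$sweeps)) {
    utils::write.csv(as.data.frame(result$sweeps$primary),
                     wr("sensitivity_primary.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(result$sweeps$secondary),
                     wr("sensitivity_secondary.csv"), row.names = FALSE)
  }
  jsonlite::write_json(falsification_as_list(result$falsification),
                       wr("falsification.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log <- list(seed = cfg$seed, threshold = cfg$threshold,
              manual_bandwidth = cfg$manual_bandwidth,
              sweep_grid = cfg$sweep_grid, alpha = cfg$alpha,
              kernel = cfg$kernel, outcomes = cfg$outcomes,
              n_cohort = cohort_size(result$cohort),
              n_placebo = cohort_size(result$placebo_cohort),
              generated = inherits(cfg$cohort %||% "generated",
                                   "cohort_config") || is.null(cfg$cohort))
  jsonlite::write_json(log, wr("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (isTRUE(cfg$make_figures)) {
    paths <- c(paths, write_analysis_figures(result, output_dir))
  }
  paths
}

rd_fit_as_list <- function(f) {
  f[c("outcome_label", "estimate", "se", "ci_low", "ci_high", "p_value",
      "bandwidth", "order", "kernel", "n_left", "n_right", "units")]
}

falsification_as_list <- function(rep) {
  safe <- function(obj, f) if (inherits(obj, "error"))
    list(error = conditionMessage(obj)) else f(obj)
  list(
    density = safe(rep$density_result, function(d)
      d[c("theta", "se", "p_value", "bin_size", "bandwidth")]),
    covariate_balance = safe(rep$covariate_fits, function(b)
      lapply(unclass(b), rd_fit_as_list)),
    placebo = safe(rep$placebo_fit, rd_fit_as_list),
    assignment_jump = safe(rep$assignment, function(a)
      rd_fit_as_list(a$jump)),
    verdicts = rep$verdicts,
    alpha = rep$alpha)
}

#' @export
print.rd_analysis <- function(x, ...) {
  cat("<rd_analysis>\n\nResults table:\n")
  print(format_results_table(x$results_table), row.names = FALSE)
  cat("\n")
  print(x$falsification)
  if (length(x$paths)) {
    cat("\nOutputs written:\n")
    for (p in x$paths) cat(" ", p, "\n")
  }
  invisible(x)
}
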