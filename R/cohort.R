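# the cohort container and its delimited-text round trip

#' Required columns of a cohort table
#' @keywords internal
COHORT_COLUMNS <- c("id", "max_score", "treated", "rrt", "icu_transfer",
                    "arrest", "death", "age", "elixhauser", "days_to_max",
                    "period", "unit")

new_cohort <- function(records, threshold, provenance = list()) {
  stopifnot(is.data.frame(records))
  structure(list(records = records, threshold = threshold,
                 provenance = provenance),
            class = "rd_cohort")
}

validate_cohort <- function(cohort, source = "<memory>") {
  df <- cohort$records
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_stage("cohort", "%s: missing required column(s): %s",
               source, paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$max_score) | df$max_score < 0 | df$max_score > 100)
  if (length(bad)) {
    stop_stage("cohort", "%s: max_score outside [0, 100] on row(s) %s",
               source, paste(utils::head(bad, 5), collapse = ", "))
  }
  for (fl in c("rrt", "icu_transfer", "arrest", "death", "treated")) {
    bad <- which(!(df[[fl]] %in% c(0, 1)))
    if (length(bad)) {
      stop_stage("cohort", "%s: column '%s' must be 0/1; bad row(s) %s",
                 source, fl, paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (anyDuplicated(df$id)) {
    stop_stage("cohort", "%s: record ids are not unique", source)
  }
  invisible(cohort)
}

#' Number of hospitalizations in a cohort
#' @param cohort an `rd_cohort`
#' @return integer count
#' @export
cohort_size <- function(cohort) nrow(cohort$records)

#' @export
print.rd_cohort <- function(x, ...) {
  df <- x$records
  above <- mean(df$max_score >= x$threshold)
  cat(sprintf("<rd_cohort> %d hospitalizations, threshold %.1f (%.1f%% at/above)\n",
              nrow(df), x$threshold, 100 * above))
  cat(sprintf("  primary composite rate: %.3f   period(s): %s\n",
              mean(composite_outcome(df, "primary")),
              paste(unique(df$period), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.rd_cohort <- function(x, ...) x$records

#' Write a cohort to delimited text
#'
#' Comma-separated, header row, one hospitalization per row. The analyzed
#' fields round-trip exactly through [read_cohort()] because the generator
#' records scores and covariates at a fixed decimal grain.
#'
#' @param cohort an `rd_cohort`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$records
  ord <- c(COHORT_COLUMNS, setdiff(names(df), COHORT_COLUMNS))
  utils::write.csv(df[, ord, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' The header must contain the documented schema columns (`id`, `max_score`,
#' `treated`, `rrt`, `icu_transfer`, `arrest`, `death`, `age`, `elixhauser`,
#' `days_to_max`, `period`, `unit`); unknown columns are preserved. Missing
#' required columns, out-of-range scores and malformed flag values are fatal
#' with row numbers.
#'
#' @param path input file path
#' @param threshold alert threshold attached to the cohort (default 65)
#' @return an `rd_cohort`
#' @export
read_cohort <- function(path, threshold = 65) {
  if (!file.exists(path)) stop_stage("cohort", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  # canonical column types: doubles for measurements (integer-valued columns
  # would otherwise be inferred as integer), integers for flags
  for (col in intersect(c("max_score", "age", "elixhauser", "days_to_max"),
                        names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in intersect(c("treated", "rrt", "icu_transfer", "arrest",
                          "death", "contaminated"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  cohort <- new_cohort(df, threshold,
                       provenance = list(source = path))
  validate_cohort(cohort, source = path)
  cohort
}
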