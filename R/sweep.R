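# bandwidth sensitivity sweeps

#' Bandwidth sensitivity sweep
#'
#' Re-estimates the discontinuity over an increasing grid of bandwidths,
#' holding every other setting fixed. Bandwidths whose one-sided fits lack
#' support are skipped with a warning.
#'
#' @inheritParams rd_estimate
#' @param h_values strictly increasing positive bandwidths (default 1..15)
#' @param kernel kernel name
#' @return an object of class `rd_sensitivity`: list with `h` (usable
#'   bandwidths), `fits` (one `rd_fit` per usable h), `skipped`
#' @export
bandwidth_sweep <- function(cohort, outcome_label, c = NULL,
                            h_values = 1:15,
                            kernel = c("triangular", "uniform"), order = 1L,
                            alpha = 0.05, vce = "hc1") {
  kernel <- match.arg(kernel)
  stopifnot(all(h_values > 0), !is.unsorted(h_values, strictly = TRUE))
  c <- c %||% cohort$threshold
  fits <- list(); hs <- numeric(0); skipped <- numeric(0)
  for (h in as.numeric(h_values)) {
    fit <- tryCatch(
      suppressMessages(rd_estimate(cohort, outcome_label, c,
                                   kernel_spec(kernel, h), order, alpha, vce)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("bandwidth h = %g skipped: %s", h,
                      conditionMessage(fit)))
      skipped <- c(skipped, h)
    } else {
      fits[[length(fits) + 1L]] <- fit
      hs <- c(hs, h)
    }
  }
  structure(list(h = hs, fits = fits, skipped = skipped,
                 outcome_label = outcome_label),
            class = "rd_sensitivity")
}

#' @export
as.data.frame.rd_sensitivity <- function(x, ...) {
  do.call(rbind, lapply(x$fits, as.data.frame))
}

#' @export
print.rd_sensitivity <- function(x, ...) {
  cat(sprintf("<rd_sensitivity> outcome %s, %d bandwidth(s)\n",
              x$outcome_label, length(x$h)))
  df <- as.data.frame(x)
  s <- if (is_binary_outcome(x$outcome_label)) 100 else 1
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  h = %5.2f  estimate %7.2f  (%6.2f to %6.2f)\n",
                df$bandwidth[i], s * df$estimate[i],
                s * df$ci_low[i], s * df$ci_high[i]))
  }
  if (length(x$skipped)) {
    cat("  skipped h:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
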