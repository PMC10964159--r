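# figure artifacts: binned proportions with fitted lines, histograms,
# sensitivity curves (regenerated, not pixel-matched to any publication)

write_analysis_figures <- function(result, output_dir) {
  cohort <- result$cohort
  cfg <- result$config
  c0 <- cfg$threshold
  paths <- character(0)
  fig <- function(name, expr) {
    p <- file.path(output_dir, name)
    grDevices::pdf(p, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(expr)
    paths <<- c(paths, p)
  }
  fig("fig_assignment.pdf", plot_assignment(cohort, c0, cfg$bin_width))
  fig("fig_binned_primary.pdf",
      plot_binned_rates(cohort, "primary", c0, cfg$bin_width,
                        result$fits[["primary.manual"]]))
  fig("fig_score_hist.pdf", plot_score_histogram(cohort, c0))
  if (!is.null(result$sweeps)) {
    fig("fig_sensitivity.pdf", plot_sensitivity(result$sweeps$primary))
  }
  paths
}

plot_assignment <- function(cohort, c0, bin_width = 1) {
  ad <- assignment_discontinuity(cohort, c0, bin_width)
  graphics::plot(ad$bins$center, ad$bins$prop_treated, pch = 19, cex = 0.6,
                 xlab = "maximum deterioration-index score",
                 ylab = "proportion treated", ylim = c(0, 1),
                 main = "Assignment discontinuity at the threshold")
  graphics::abline(v = c0, lty = 2)
}

plot_binned_rates <- function(cohort, outcome_label, c0, bin_width, fit) {
  br <- bin_outcome_rates(cohort, outcome_label, bin_width, c0)
  graphics::plot(br$center, br$rate, pch = 19, cex = 0.6,
                 xlab = "maximum deterioration-index score",
                 ylab = sprintf("%s event rate", outcome_label),
                 main = sprintf("Binned %s rates with local fit",
                                outcome_label))
  graphics::abline(v = c0, lty = 2)
  if (!is.null(fit)) {
    h <- fit$bandwidth
    spec <- kernel_spec(fit$kernel, h)
    for (side in c("below", "above")) {
      sf <- tryCatch(fit_side(cohort, outcome_label, side, c0, spec,
                              fit$order),
                     error = function(e) NULL)
      if (is.null(sf)) next
      xs <- if (side == "below") seq(c0 - h, c0, length.out = 50)
            else seq(c0, c0 + h, length.out = 50)
      ys <- drop(outer(xs - c0, 0:fit$order, `^`) %*% sf$coef)
      graphics::lines(xs, ys, lwd = 2)
    }
  }
}

plot_score_histogram <- function(cohort, c0, bin_width = 1) {
  hs <- score_histogram(cohort, bin_width, c0)
  graphics::plot(hs$center, hs$count, type = "h", lwd = 3, lend = 1,
                 xlab = "maximum deterioration-index score", ylab = "count",
                 main = "Running-variable distribution")
  graphics::abline(v = c0, lty = 2)
}

plot_sensitivity <- function(sweep) {
  df <- as.data.frame(sweep)
  s <- if (is_binary_outcome(sweep$outcome_label)) 100 else 1
  graphics::plot(df$bandwidth, s * df$estimate, pch = 19,
                 ylim = range(s * c(df$ci_low, df$ci_high)),
                 xlab = "bandwidth (score points)",
                 ylab = "discontinuity estimate",
                 main = sprintf("Bandwidth sensitivity (%s outcome)",
                                sweep$outcome_label))
  graphics::arrows(df$bandwidth, s * df$ci_low, df$bandwidth, s * df$ci_high,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 2)
}
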