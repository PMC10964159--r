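# internal helpers shared across modules

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' One master seed is split into named streams so that, e.g., adding a
#' covariate to the generator does not perturb the score draws. The split is
#' a fixed integer hash of the label folded into the master seed, kept below
#' 2^31 so it is a valid R seed.
#'
#' @param seed master integer seed
#' @param label character stream name
#' @return an integer seed
#' @keywords internal
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# snap to the grain and canonicalize the double so values survive a
# text round trip bit-for-bit (round(x/0.1)*0.1 can sit one ulp off the
# double that parsing "27.9" produces)
round_to <- function(x, grain) round(round(x / grain) * grain, 10)

`%||%` <- function(a, b) if (is.null(a)) b else a

# format a p-value the way clinical tables print them (".03", "<.001")
format_pvalue <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.2f", p)))
}

stop_stage <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
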