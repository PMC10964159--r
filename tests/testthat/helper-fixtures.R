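# shared fixtures and independent oracles for the test suite

small_config <- function(n = 2000, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# a tiny deterministic cohort around the cutoff built from literal vectors
hand_cohort <- function(x, y, c = 65) {
  n <- length(x)
  df <- data.frame(
    id = sprintf("h%03d", seq_len(n)),
    max_score = x,
    treated = as.integer(x >= c),
    rrt = as.integer(y), icu_transfer = 0L, arrest = 0L, death = 0L,
    age = 70, elixhauser = 5, days_to_max = 2,
    period = "active", unit = "u1", contaminated = 0L,
    stringsAsFactors = FALSE
  )
  rddalert:::new_cohort(df, c)
}

# independent closed-form weighted-least-squares oracle: solves the normal
# equations directly; deliberately a different code path from fit_side
wls_oracle <- function(x, y, w, c, order) {
  keep <- w > 0
  X <- outer(x[keep] - c, 0:order, `^`)
  drop(solve(t(X) %*% diag(w[keep]) %*% X,
             t(X) %*% diag(w[keep]) %*% y[keep]))
}

ols_oracle <- function(x, y, c, order) {
  wls_oracle(x, y, rep(1, length(x)), c, order)
}

# Frozen reference bandwidths from an independent implementation of the same
# published plug-in formulas (numpy, written separately from the R code).
# No independently maintained CCT selector is installable in this
# environment, so the reference is a synthetic stand-in computed once from
# the second implementation and frozen here.
CCT_ORACLE <- list(
  list(n = 3000, seed = 101, tau = -0.104, outcome = "primary", order = 1,
       h_ref = 9.3533861170),
  list(n = 5000, seed = 202, tau = -0.05, outcome = "secondary", order = 1,
       h_ref = 9.1093886145),
  list(n = 3000, seed = 303, tau = -0.104, outcome = "primary", order = 2,
       h_ref = 11.6788085609)
)
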