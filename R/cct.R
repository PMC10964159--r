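# MSE-optimal bandwidth selection for the sharp RD estimator
# (Calonico-Cattaneo-Titiunik style plug-in selector)

#' MSE-optimal bandwidth for the sharp RD estimator
#'
#' Plug-in selector for the bandwidth minimizing the asymptotic mean squared
#' error of the local polynomial discontinuity estimator of order `p`:
#'
#' \deqn{h = \left(\frac{V}{2(p+1)\,(B^2 + R)\, n}\right)^{1/(2p+3)}}
#'
#' where `V = v_K (sigma2_above + sigma2_below) / f(c)` is the asymptotic
#' variance constant and `B = b_K (m^(p+1)_above - (-1)^(p+1)
#' m^(p+1)_below) / (p+1)!` the bias constant, with exact boundary kernel
#' constants `b_K`, `v_K` (see `kernel_constants`). Pilot quantities: the
#' density at the cutoff from a Gaussian kernel density estimate with
#' Silverman's bandwidth; side-wise conditional variances from the residuals
#' of uniform-kernel local linear fits in a pilot window `1.84 sd(x)
#' n^(-1/5)`; and the (p+1)-th derivatives from global side-wise polynomial
#' fits of order `p + 2`. The regularization term `R = 3 (V_b^above +
#' V_b^below)` (variance of the estimated bias constant) guards against
#' near-zero curvature and is on by default. A single symmetric bandwidth is
#' returned.
#'
#' The selector is exactly equivariant under affine rescaling of the score:
#' multiplying scores and cutoff by `k` multiplies `h` by `k`, and `h`
#' shrinks at the rate `n^(-1/(2p+3))`.
#'
#' @inheritParams fit_side
#' @param kernel kernel name used by the eventual RD fit
#' @param regularization logical; include the CCT-style regularization term
#' @param details logical; return the pilot quantities alongside `h`
#' @return the bandwidth (score units), or a list if `details = TRUE`
#' @export
cct_bandwidth <- function(cohort, outcome_label, c = NULL,
                          kernel = c("triangular", "uniform"), order = 1L,
                          regularization = TRUE, details = FALSE) {
  kernel <- match.arg(kernel)
  p <- as.integer(order)
  df <- if (inherits(cohort, "rd_cohort")) cohort$records else cohort
  c <- c %||% cohort$threshold
  y <- outcome_vector(cohort, outcome_label)
  keep <- !is.na(y) & !is.na(df$max_score)
  x <- df$max_score[keep]; y <- y[keep]
  n <- length(x)
  xb <- x[x < c]; yb <- y[x < c]
  xa <- x[x >= c]; ya <- y[x >= c]
  if (length(xb) < p + 4 || length(xa) < p + 4) {
    stop_stage("cct", "need at least %d records per side for the pilot fits",
               p + 4L)
  }

  # density at the cutoff (Silverman rule, Gaussian kernel)
  bw0 <- 0.9 * min(stats::sd(x), stats::IQR(x) / 1.34) * n^(-1 / 5)
  f_c <- mean(stats::dnorm((x - c) / bw0)) / bw0

  # side-wise conditional variance at the cutoff: residual variance of a
  # local linear pilot fit in a uniform window
  h_pilot <- 1.84 * stats::sd(x) * n^(-1 / 5)
  sig2_b <- pilot_variance(xb, yb, c, h_pilot)
  sig2_a <- pilot_variance(xa, ya, c, h_pilot)

  # (p+1)-th derivative estimates from global polynomial fits of order p+2;
  # the basis coefficient of degree p+1 equals m^(p+1)(c) / (p+1)!
  gb <- global_curvature(xb, yb, c, p)
  ga <- global_curvature(xa, ya, c, p)

  kc <- kernel_constants(kernel, p)
  sgn <- (-1)^(p + 1)
  B <- kc$b * (ga$coef - sgn * gb$coef)
  V_B <- kc$b^2 * (ga$var + gb$var)
  R <- if (regularization) 3 * V_B else 0
  V <- kc$v * (sig2_a + sig2_b) / f_c

  denom <- 2 * (p + 1) * (B^2 + R)
  if (!is.finite(denom) || denom <= 0) {
    stop_stage("cct", "degenerate pilot fits (zero curvature and no regularization)")
  }
  h <- (V / (denom * n))^(1 / (2 * p + 3))
  if (details) {
    list(h = h, f_c = f_c, sigma2_below = sig2_b, sigma2_above = sig2_a,
         deriv_below = gb$coef * factorial(p + 1),
         deriv_above = ga$coef * factorial(p + 1),
         B = B, V = V, R = R, n = n, kernel = kernel, order = p,
         regularization = regularization)
  } else h
}

# residual variance of y ~ (x - c) among the pilot-window points nearest the
# cutoff; the window widens to the 5 nearest points if too narrow
pilot_variance <- function(x, y, c, h_pilot) {
  d <- abs(x - c)
  inw <- d < h_pilot
  if (sum(inw) < 5) inw <- rank(d, ties.method = "first") <= 5
  xs <- x[inw] - c; ys <- y[inw]
  fit <- stats::lm.fit(cbind(1, xs), ys)
  dof <- max(length(ys) - 2L, 1L)
  sum(fit$residuals^2) / dof
}

# OLS coefficient (and its homoskedastic variance) of degree p+1 in a global
# side-wise polynomial of order p+2 on the centered score; the basis is
# standardized before solving so the selector stays well conditioned under
# affine rescaling of the score, and coefficients are mapped back exactly
global_curvature <- function(x, y, c, p) {
  q <- p + 2L
  s <- stats::sd(x - c)
  if (!is.finite(s) || s <= 0) stop_stage("cct", "degenerate score spread")
  X <- outer((x - c) / s, 0:q, `^`)
  XtX <- crossprod(X)
  A <- tryCatch(solve(XtX), error = function(e) {
    stop_stage("cct", "singular global polynomial design (order %d)", q)
  })
  beta <- drop(A %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  dof <- max(length(y) - q - 1L, 1L)
  sigma2 <- sum(e^2) / dof
  j <- p + 2L  # index of the degree-(p+1) coefficient (1-based)
  list(coef = beta[j] / s^(p + 1), var = sigma2 * A[j, j] / s^(2 * (p + 1)))
}
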