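# kernel weights and the boundary local-polynomial kernel constants

#' Kernel specification for local polynomial fits
#'
#' @param name `"triangular"` (weight declining linearly from 1 at the
#'   cutoff to 0 at distance `h`) or `"uniform"`
#' @param h bandwidth in score units, > 0; kernel support is open at
#'   `|x - c| = h`
#' @return an object of class `kernel_spec`
#' @export
kernel_spec <- function(name = c("triangular", "uniform"), h) {
  name <- match.arg(name)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("bandwidth h must be a single positive number", call. = FALSE)
  }
  structure(list(name = name, h = h), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s, h = %g\n", x$name, x$h)); invisible(x)
}

#' Kernel weight of a score relative to the cutoff
#'
#' Triangular: `max(0, 1 - |x - c| / h)`; uniform: `1{|x - c| < h}`.
#'
#' @param x score value(s)
#' @param c cutoff
#' @param spec a [kernel_spec()]
#' @return weights in \[0, 1\], vectorized over `x`
#' @export
kernel_weight <- function(x, c, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  u <- abs(x - c) / spec$h
  switch(spec$name,
         triangular = pmax(0, 1 - u),
         uniform = as.numeric(u < 1))
}

# Exact boundary constants of the local polynomial estimator of order p at a
# cutoff: with basis r(u) = (1, u, ..., u^p)' and one-sided kernel moments
#   Gamma = int_0^1 K(u) r r' du,  vartheta = int_0^1 K(u) u^(p+1) r du,
#   Psi   = int_0^1 K(u)^2 r r' du,
# the intercept bias constant is b = e0' Gamma^-1 vartheta and the variance
# constant is v = e0' Gamma^-1 Psi Gamma^-1 e0. Moments are rational:
#   triangular: int (1-u) u^j = 1/((j+1)(j+2)), int (1-u)^2 u^j = 2/((j+1)(j+2)(j+3))
#   uniform:    1/(j+1) for both K and K^2.
# For p = 1, triangular: b = -1/10, v = 24/5 (the constants quoted in the
# McCrary density-test variance formula).
kernel_constants <- function(name, p) {
  m1 <- switch(name,
               triangular = function(j) 1 / ((j + 1) * (j + 2)),
               uniform = function(j) 1 / (j + 1))
  m2 <- switch(name,
               triangular = function(j) 2 / ((j + 1) * (j + 2) * (j + 3)),
               uniform = function(j) 1 / (j + 1))
  idx <- 0:p
  G <- outer(idx, idx, function(i, j) m1(i + j))
  th <- vapply(idx, function(j) m1(j + p + 1), numeric(1))
  Ps <- outer(idx, idx, function(i, j) m2(i + j))
  Gi <- solve(G)
  list(b = drop(Gi %*% th)[1], v = (Gi %*% Ps %*% Gi)[1, 1])
}
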