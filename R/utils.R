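# Internal numerical helpers shared across modules.

#' Evaluate a polynomial with ascending coefficients
#' @param coefs numeric vector c(c0, c1, ...) for c0 + c1*x + c2*x^2 + ...
#' @param x numeric vector
#' @return numeric vector of polynomial values
#' @keywords internal
polyval_asc <- function(coefs, x) {
  out <- rep(0, length(x))
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

# Antiderivative coefficients of an ascending-coefficient polynomial.
poly_antideriv <- function(coefs) {
  c(0, coefs / seq_along(coefs))
}

#' Central-difference derivative on a uniform grid
#'
#' Interior points use central differences; endpoints one-sided differences.
#' All dynamics code (generator and inverse dynamics) shares this routine so
#' that synthetic trials are dynamically consistent by construction.
#' @param x numeric vector or matrix (columns differentiated)
#' @param dt sampling interval in seconds
#' @keywords internal
central_diff <- function(x, dt) {
  if (is.matrix(x)) return(apply(x, 2, central_diff, dt = dt))
  n <- length(x)
  if (n < 3) stop("central_diff needs at least 3 samples")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Trapezoidal quadrature weights for a uniform grid of n nodes spaced dt.
trapz_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1, n)] <- dt / 2
  w
}

trapz <- function(y, dt) sum(trapz_weights(length(y), dt) * y)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(k)) %% 2147483587) + 1L
}

# Linear interpolation with constant extrapolation at the edges.
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Resample a stance-indexed trace onto a 0..100% grid with `n` points.
resample_pct <- function(pct_in, y, n = 101L) {
  grid <- seq(0, 100, length.out = n)
  stats::approx(pct_in, y, xout = grid, rule = 2)$y
}

stance_pct_grid <- function(n = 101L) seq(0, 100, length.out = n)
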