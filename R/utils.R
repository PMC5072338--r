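# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.005 -> 0.01), as used when
#' reporting percentages to two decimals. Base [round()] rounds half to even,
#' which is unsuitable for reproducing printed tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Stationary AR(1) Gaussian noise
#'
#' Draws a mean-zero first-order autoregressive series with marginal standard
#' deviation `sd` (innovation variance is scaled by `1 - rho^2` so the
#' marginal variance does not depend on `rho`). Uses the current RNG stream.
#'
#' @param n Series length.
#' @param sd Marginal standard deviation (>= 0).
#' @param rho Lag-1 autocorrelation in (-1, 1).
#' @return Numeric vector of length `n`.
#' @export
ar1_noise <- function(n, sd, rho = 0) {
  stopifnot(n >= 1, sd >= 0, abs(rho) < 1)
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, sd = sd)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  x
}

# lag-1 autocorrelation of a residual vector, computed within blocks
# (blocks = independent series, e.g. macrocosms)
lag1_rho <- function(r, block) {
  num <- 0; den <- 0
  for (idx in split(seq_along(r), block)) {
    x <- r[idx]
    if (length(x) < 3) next
    num <- num + sum(x[-1] * x[-length(x)])
    den <- den + sum(x^2)
  }
  if (den == 0) return(0)
  max(min(num / den, 0.98), -0.98)
}
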