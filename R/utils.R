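# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Display rounding used for proportional tidal volume distribution:
#' nearest unit with ties going away from zero (so 8.5 -> 9), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Cumulative trapezoidal integral of y over uniformly sampled grid dt.
# Returns a vector the same length as y, starting at 0.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * dt))
}

trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2) * dt
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103L + as.numeric(k) * 12289) %% 2147483647
}
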