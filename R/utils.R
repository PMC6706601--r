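# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed fans out into
# reproducible per-spot / per-sample seeds. Arithmetic in doubles (exact
# below 2^53), folded back into the 32-bit signed range.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629
  as.integer(s) + 1L
}

# Lognormal multiplicative noise with mean exactly 1 and the requested
# coefficient of variation.
lognormal_multiplier <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quadratic (3-point parabola) apex interpolation around grid index i.
# Returns the refined apex position and height.
parabola_apex <- function(mz, intensity, i) {
  n <- length(mz)
  if (i <= 1L || i >= n) return(c(mz = mz[i], height = intensity[i]))
  y0 <- intensity[i - 1L]; y1 <- intensity[i]; y2 <- intensity[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0 || !is.finite(denom)) {
    return(c(mz = mz[i], height = y1))
  }
  delta <- 0.5 * (y0 - y2) / denom
  step <- mz[i + 1L] - mz[i]
  c(mz = mz[i] + delta * step,
    height = y1 - 0.25 * (y0 - y2) * delta)
}
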