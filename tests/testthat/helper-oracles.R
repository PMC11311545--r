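# Independent oracles kept deliberately separate from the package internals.

# Ordinary least squares via the explicit normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  det <- n * sxx - sx^2
  a1 <- (n * sxy - sx * sy) / det
  a0 <- (sy * sxx - sx * sxy) / det
  c(a0 = a0, a1 = a1)
}

# Term-by-term transcription of the double-IDMS ratio-of-ratios estimator,
# in a different algebraic arrangement than the implementation.
emd_oracle <- function(m_x, m_y, m_zc, m_yc, r_b, r_bc, w_zc) {
  t1 <- m_y / m_x
  t2 <- m_zc / m_yc
  t3 <- r_b / r_bc
  unname(w_zc * t1 * t2 * t3)
}

# random valid emd pair
random_emd_pair <- function() {
  emd_pair(m_x = uq(runif(1, 100, 1000)), m_y = uq(runif(1, 100, 1000)),
           m_zc = uq(runif(1, 100, 1000)), m_yc = uq(runif(1, 100, 1000)),
           r_b = uq(runif(1, 0.5, 2)), r_bc = uq(runif(1, 0.5, 2)),
           w_zc = uq(runif(1, 1, 50)))
}

scale_ratios <- function(pair, f) {
  emd_pair(m_x = pair$m_x, m_y = pair$m_y, m_zc = pair$m_zc,
           m_yc = pair$m_yc,
           r_b = uq(pair$r_b$value * f, pair$r_b$u),
           r_bc = uq(pair$r_bc$value * f, pair$r_bc$u),
           w_zc = pair$w_zc)
}

scale_series_ratios <- function(series, f) {
  b <- series$blends
  b$r_obs <- b$r_obs * f
  addition_series(b, w_z = series$w_z, isotopes = series$isotopes)
}
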