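# Independent oracles and shared fixtures for the test suite.

# Brute-force demodulation oracle: per-pixel linear least squares of
# I_k = a + b cos(theta_k) + c sin(theta_k), independent of the DFT path.
demod_oracle <- function(stack) {
  theta <- 2 * pi * (seq_len(stack$config$n_phase_steps) - 1) /
    stack$config$n_phase_steps
  d <- dim(stack$frames)
  X <- cbind(1, cos(theta), sin(theta))
  flat <- matrix(stack$frames, nrow = d[1])
  beta <- qr.solve(X, flat)              # 3 x npix
  dc <- matrix(beta[1, ], d[2], d[3])
  ac <- matrix(sqrt(beta[2, ]^2 + beta[3, ]^2), d[2], d[3])
  phase <- matrix(atan2(beta[3, ], beta[2, ]), d[2], d[3])
  list(dc = dc, ac = ac, raw_phase = phase)
}

# closed-form phasor of a mono-exponential decay
mono_phasor <- function(tau, frequency_mhz) {
  w <- 2 * pi * frequency_mhz * 1e-3
  m <- 1 / sqrt(1 + (w * tau)^2)
  list(g = m * cos(atan(w * tau)), s = m * sin(atan(w * tau)))
}

test_config <- function(...) instrument_config(...)

# small default image for pipeline tests
px8 <- c(8, 8)
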