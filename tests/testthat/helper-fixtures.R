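# Shared fixtures and independent oracles used across the suite.

# Small, fast simulation configuration for structural tests.
tiny_config <- function(...) {
  defaults <- list(n_subjects = 3, n_sessions = 2, n_timepoints = 64,
                   grid_dims = c(8, 8, 8), rng_seed = 42L)
  do.call(simulation_config, modifyList(defaults, list(...)))
}

# Direct-summation DFT: the oracle for compute_spectrum().
naive_dft_magnitudes <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))
  }, 0)
}

# Explicit normal-equations solve: the oracle for regress_out().
normal_equations_residual <- function(y, x) {
  beta <- solve(t(x) %*% x, t(x) %*% y)
  y - x %*% beta
}

# A cosine landing exactly on DFT bin k (no leakage).
exact_tone <- function(n, k, amplitude = 1, phase = 0) {
  amplitude * cos(2 * pi * k * (0:(n - 1)) / n + phase)
}
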