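# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Interleaved conjugate rotation eigenvalues for in-band frequencies.
rotation_eigvals <- function(freqs, dt = 2, modulus = 1) {
  th <- 2 * pi * freqs * dt
  as.vector(rbind(modulus * exp(1i * th), modulus * exp(-1i * th)))
}

# Small noiseless multi-sine cohort (fast DMD, exact in-band structure).
small_sine_cohort <- function(n_per_group = 2, R = 20, T = 80, noise_sd = 0,
                              out_of_band_sd = 0, seed = 42, effects = list()) {
  generate_sinusoid_cohort(cohort_spec(
    n_per_group = n_per_group, R = R, T = T, noise_sd = noise_sd,
    out_of_band_sd = out_of_band_sd, seed = seed, effects = effects))
}

# Exact linear-system subject driven by in-band rotations.
small_linear_subject <- function(R = 12, T = 50, freqs = c(0.03, 0.06), seed = 5) {
  co <- generate_linear_system_cohort(1, R = R, T = T, dt = 2,
                                      eigvals = rotation_eigvals(freqs), seed = seed)
  co$subjects[[1]]
}

# Feature table with planted group-separating columns among pure noise.
planted_feature_table <- function(n_per_group = 20, p = 30, planted = 1:3,
                                  delta = 2, sd = 1, seed = 7) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), each = n_per_group)
  x <- matrix(rnorm(2 * n_per_group * p, sd = sd), 2 * n_per_group, p)
  for (j in planted) x[labels == 1L, j] <- x[labels == 1L, j] + delta
  feature_table(x, labels)
}

# The five-effect planted cohort used for recovery and benchmark checks:
# equal-width sub-band effects of comparable strength, mixed directions.
planted_effects <- function() {
  list(effect_spec(10,  c(0.01, 0.04), +1, 0.5),
       effect_spec(60,  c(0.04, 0.07), +1, 0.5),
       effect_spec(110, c(0.07, 0.10), -1, 0.5),
       effect_spec(160, c(0.04, 0.07), +1, 0.5),
       effect_spec(210, c(0.01, 0.04), -1, 0.5))
}
planted_regions <- function() c(10L, 60L, 110L, 160L, 210L)
planted_signs <- function() c(1, 1, -1, 1, -1)
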