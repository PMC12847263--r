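test_that("cohort and effect specs validate their inputs", {
  expect_error(cohort_spec(T = 1), "T")
  expect_error(cohort_spec(dt = -1), "dt")
  expect_error(cohort_spec(freq_grid = c(0.05, 0.3), dt = 2), "Nyquist")
  expect_error(effect_spec(1, c(0.04, 0.01), 1, 0.5), "increasing")
  expect_error(effect_spec(1, c(0.01, 0.04), 2, 0.5), "direction")
  expect_error(effect_spec(1, c(0.01, 0.04), 1, 0), "nonzero")
  # effect band with no oscillator to modulate is rejected
  expect_error(cohort_spec(R = 4, effects = list(effect_spec(2, c(0.001, 0.002), 1, 0.5))),
               "no freq_grid oscillator")
  expect_error(cohort_spec(R = 2, effects = list(effect_spec(5, c(0.01, 0.04), 1, 0.5))),
               "out of range")
})

test_that("a noiseless single-frequency spec yields a pure sine of the requested peak", {
  sp <- cohort_spec(n_per_group = 1, R = 1, T = 200, dt = 2, freq_grid = 0.05,
                    base_amplitude = 1, noise_sd = 0, out_of_band_sd = 0, seed = 3)
  co <- generate_sinusoid_cohort(sp)
  x <- co$subjects[[1]]$values[, 1]
  tt <- (0:199) * 2
  # recover phase by least squares on the two quadratures; residual must vanish
  basis <- cbind(sin(2 * pi * 0.05 * tt), cos(2 * pi * 0.05 * tt))
  fit <- lm.fit(basis, x)
  expect_lt(max(abs(fit$residuals)), 1e-12)
  expect_equal(sqrt(sum(fit$coefficients^2)), 1, tolerance = 1e-12)
})

test_that("cohorts have the requested dimensions, labels and determinism", {
  sp <- cohort_spec(n_per_group = 3, R = 7, T = 30, seed = 9)
  co <- generate_sinusoid_cohort(sp)
  expect_length(co$subjects, 6)
  expect_equal(co$labels, rep(c(0L, 1L), each = 3))
  expect_equal(dim(co$subjects[[1]]$values), c(30, 7))
  co2 <- generate_sinusoid_cohort(sp)
  expect_identical(co$subjects, co2$subjects)
  # different seed, different subjects
  co3 <- generate_sinusoid_cohort(cohort_spec(n_per_group = 3, R = 7, T = 30, seed = 10))
  expect_false(identical(co$subjects[[1]]$values, co3$subjects[[1]]$values))
})

test_that("planted in-band amplitude ratio is exact on noiseless cohorts", {
  # with noise_sd = 0 the patient/control amplitude ratio in the effect band
  # equals 1 + relative_magnitude exactly
  ef <- effect_spec(2, c(0.01, 0.04), +1, 0.5)
  sp <- cohort_spec(n_per_group = 1, R = 3, T = 400, dt = 2, noise_sd = 0,
                    out_of_band_sd = 0, effects = list(ef), seed = 21)
  co <- generate_sinusoid_cohort(sp)
  # joint quadrature fit over the whole frequency grid: the signal lies
  # exactly in this span, so per-frequency amplitudes are recovered exactly
  amp_at <- function(x, f) {
    tt <- (seq_along(x) - 1) * 2
    b <- do.call(cbind, lapply(sp$freq_grid, function(g)
      cbind(sin(2 * pi * g * tt), cos(2 * pi * g * tt))))
    cf <- lm.fit(b, x)$coefficients
    i <- which(sp$freq_grid == f)
    sqrt(sum(cf[c(2 * i - 1, 2 * i)]^2))
  }
  in_band <- sp$freq_grid[sp$freq_grid >= 0.01 & sp$freq_grid <= 0.04]
  for (f in in_band) {
    r <- amp_at(co$subjects[[2]]$values[, 2], f) / amp_at(co$subjects[[1]]$values[, 2], f)
    expect_equal(r, 1.5, tolerance = 1e-6)
  }
  # untouched region and out-of-effect-band frequencies keep ratio 1
  expect_equal(amp_at(co$subjects[[2]]$values[, 1], 0.015) /
                 amp_at(co$subjects[[1]]$values[, 1], 0.015), 1, tolerance = 1e-6)
  expect_equal(amp_at(co$subjects[[2]]$values[, 2], 0.055) /
                 amp_at(co$subjects[[1]]$values[, 2], 0.055), 1, tolerance = 1e-6)
})

test_that("planted effects raise patient-group spectral power only in the target region", {
  ef <- effect_spec(5, c(0.01, 0.04), +1, 0.5)
  sp <- cohort_spec(n_per_group = 20, R = 8, T = 140, effects = list(ef), seed = 31)
  co <- generate_sinusoid_cohort(sp)
  in_band <- sp$freq_grid[sp$freq_grid >= 0.01 & sp$freq_grid <= 0.04]
  pgram_power <- function(x, freqs) {
    sp_ <- stats::spec.pgram(stats::ts(x, deltat = 2), plot = FALSE, taper = 0,
                             detrend = FALSE)
    sum(sp_$spec[vapply(freqs, function(f) which.min(abs(sp_$freq - f)), 1L)])
  }
  pow <- t(vapply(co$subjects, function(s) {
    vapply(seq_len(8), function(j) pgram_power(s$values[, j], in_band), numeric(1))
  }, numeric(8)))
  gap <- colMeans(pow[co$labels == 1, ]) / colMeans(pow[co$labels == 0, ])
  expect_gt(gap[5], 1.5)           # planted region clearly elevated
  expect_true(all(abs(gap[-5] - 1) < 0.3))  # others match between groups
})

test_that("most values fall inside the target signal scale under defaults", {
  co <- fixture("scale_cohort", generate_sinusoid_cohort(
    cohort_spec(n_per_group = 5, R = 30, T = 140, seed = 17)))
  vals <- unlist(lapply(co$subjects, function(s) s$values))
  expect_gte(mean(vals >= -10 & vals <= 10), 0.95)
  expect_true(all(vals >= -50 & vals <= 50))
})

test_that("linear-system cohorts follow the prescribed dynamics exactly", {
  # scalar geometric decay
  co <- generate_linear_system_cohort(1, R = 1, T = 8, dt = 1, eigvals = 0.5, seed = 2)
  x <- co$subjects[[1]]$values[, 1]
  expect_equal(x[-1] / x[-8], rep(0.5, 7), tolerance = 1e-12)
  # rotation pair: every region is a pure 0.05 Hz sinusoid
  sub <- small_linear_subject(R = 5, T = 60, freqs = 0.05, seed = 4)
  tt <- (0:59) * 2
  basis <- cbind(sin(2 * pi * 0.05 * tt), cos(2 * pi * 0.05 * tt))
  for (j in 1:5) {
    expect_lt(max(abs(lm.fit(basis, sub$values[, j])$residuals)), 1e-10)
  }
  # determinism
  co1 <- generate_linear_system_cohort(3, R = 6, T = 20, dt = 2,
                                       eigvals = rotation_eigvals(0.03), seed = 11)
  co2 <- generate_linear_system_cohort(3, R = 6, T = 20, dt = 2,
                                       eigvals = rotation_eigvals(0.03), seed = 11)
  expect_identical(co1$subjects, co2$subjects)
})

test_that("linear-system generator rejects invalid spectra", {
  expect_error(generate_linear_system_cohort(1, 4, 10, 2, c(0.5 + 0.2i), seed = 1),
               "conjugate")
  expect_error(generate_linear_system_cohort(1, 4, 10, 2, c(1.5), seed = 1),
               "moduli")
  expect_error(generate_linear_system_cohort(1, 1, 10, 2, rotation_eigvals(0.05), seed = 1),
               "at least")
})

test_that("cohorts round-trip through the TSV + manifest format", {
  dir <- withr::local_tempdir()
  ef <- effect_spec(2, c(0.01, 0.04), +1, 0.5)
  co <- small_sine_cohort(n_per_group = 2, R = 4, T = 20, noise_sd = 0.3,
                          seed = 8, effects = list(ef))
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_equal(co2$labels, co$labels)
  for (i in seq_along(co$subjects)) {
    expect_equal(co2$subjects[[i]]$values, co$subjects[[i]]$values, tolerance = 1e-12)
  }
  expect_length(co2$truth, 1)
  expect_equal(co2$truth[[1]]$region_index, 2L)
})
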