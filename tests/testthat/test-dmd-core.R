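test_that("snapshot pairs are the one-step-shifted column arrangement", {
  ts <- roi_timeseries(rbind(c(1, 2), c(2, 4), c(4, 8)), dt = 1)
  pair <- build_snapshots(ts)
  expect_equal(pair$X, unname(rbind(c(1, 2), c(2, 4))))
  expect_equal(pair$Xp, unname(rbind(c(2, 4), c(4, 8))))
  expect_equal(pair$Xp[, 1], pair$X[, 2])
  # minimal T = 2 gives single-column snapshots
  p2 <- build_snapshots(roi_timeseries(rbind(1:3, 4:6), dt = 1))
  expect_equal(dim(p2$X), c(3L, 1L))
  expect_equal(dim(p2$Xp), c(3L, 1L))
  expect_error(roi_timeseries(matrix(1, 1, 3), dt = 1), "2 time points")
})

test_that("exact DMD recovers the generating map of simple linear systems", {
  # scalar geometric decay: single eigenvalue 0.5
  ts <- roi_timeseries(cbind(2 ^ -(0:5)), dt = 1)
  d <- exact_dmd(build_snapshots(ts))
  expect_equal(d$rank, 1L)
  expect_lt(abs(d$eigvals[1] - 0.5), 1e-10)
  # planted rotation pair at 0.05 Hz, dt = 2
  sub <- small_linear_subject(R = 10, T = 50, freqs = 0.05, seed = 6)
  d2 <- exact_dmd(build_snapshots(sub))
  target <- sort(rotation_eigvals(0.05))
  got <- sort(d2$eigvals)
  expect_lt(max(abs(got - target)), 1e-8)
  expect_equal(d2$freqs, c(0.05, 0.05), tolerance = 1e-10)
})

test_that("eigenvalue recovery matches planted spectra by nearest-neighbour matching", {
  freqs <- c(0.02, 0.05, 0.08)
  sub <- small_linear_subject(R = 15, T = 60, freqs = freqs, seed = 13)
  d <- exact_dmd(build_snapshots(sub))
  planted <- rotation_eigvals(freqs)
  expect_equal(d$rank, length(planted))
  err <- vapply(planted, function(z) min(Mod(d$eigvals - z)), numeric(1))
  expect_lt(max(err), 1e-8)
})

test_that("degenerate and truncated decompositions behave as specified", {
  zero_ts <- roi_timeseries(matrix(0, 5, 3), dt = 1)
  expect_error(exact_dmd(build_snapshots(zero_ts)), "all-zero")
  sub <- small_linear_subject(R = 8, T = 40, freqs = c(0.03, 0.06), seed = 3)
  d <- exact_dmd(build_snapshots(sub), rank = 2)
  expect_equal(d$rank, 2L)
  expect_error(exact_dmd(build_snapshots(sub), rank = 30), "rank")
})

test_that("mode frequencies follow the principal-branch log formula", {
  expect_equal(mode_frequencies(1 + 0i, dt = 2), 0)
  expect_equal(mode_frequencies(exp(1i * 0.2 * pi), dt = 2), 0.05, tolerance = 1e-12)
  # conjugate pair maps to one frequency
  z <- 0.9 * exp(1i * 0.3)
  f <- mode_frequencies(c(z, Conj(z)), dt = 2)
  expect_equal(f[1], f[2])
  # bounds: any eigenvalue lands in [0, Nyquist]
  set.seed(1)
  zs <- complex(real = rnorm(50), imaginary = rnorm(50))
  fs <- suppressWarnings(mode_frequencies(zs, dt = 2))
  expect_true(all(fs >= 0 & fs <= 0.25 + 1e-12))
  expect_error(mode_frequencies(c(1, 0), dt = 2), "zero eigenvalue")
  expect_warning(mode_frequencies(-0.5 + 0i, dt = 2), "Nyquist")
})

test_that("mode amplitudes are squared column norms and sum over region powers", {
  phi <- cbind(c(3 + 0i, 0 + 4i))
  expect_equal(mode_amplitudes(phi), 25)
  expect_equal(mode_amplitudes(cbind(c(0 + 0i, 0 + 0i))), 0)
  set.seed(2)
  Z <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), 8, 5)
  expect_equal(unname(rowSums(region_mode_power(Z))), unname(mode_amplitudes(Z)),
               tolerance = 1e-10)
})

test_that("conjugate symmetry holds for decompositions of real data", {
  co <- small_sine_cohort(n_per_group = 1, R = 10, T = 60, noise_sd = 0.3, seed = 19)
  d <- exact_dmd(build_snapshots(co$subjects[[1]]))
  lam <- d$eigvals
  nonreal <- abs(Im(lam)) > 1e-10
  # eigenvalues closed under conjugation
  for (z in lam[nonreal]) expect_lt(min(Mod(lam - Conj(z))), 1e-8)
  # conjugate partners carry equal amplitudes
  for (i in which(nonreal)) {
    j <- which.min(Mod(lam - Conj(lam[i])))
    expect_equal(d$amplitudes[i], d$amplitudes[j], tolerance = 1e-10)
  }
})

test_that("band filtering keeps exactly the in-band modes, in conjugate pairs", {
  sub <- small_linear_subject(R = 12, T = 60, freqs = c(0.005, 0.05, 0.2), seed = 23)
  d <- exact_dmd(build_snapshots(sub))
  keep <- band_filter_modes(d, c(0.01, 0.1))
  expect_equal(sort(unique(round(d$freqs[keep$indices], 10))), 0.05)
  expect_length(keep$indices, 2)  # the conjugate pair travels together
  # identity filter keeps everything
  expect_length(band_filter_modes(d, c(0, 0.25))$indices, d$rank)
  expect_warning(empty <- band_filter_modes(d, c(0.11, 0.12)), "no modes")
  expect_length(empty$indices, 0)
  expect_error(band_filter_modes(d, c(0.1, 0.5)), "Nyquist")
})

test_that("reconstruction is the identity at t = 0 and exact on linear systems", {
  # full-rank square mode matrix: Phi pinv(Phi) = I
  co <- small_sine_cohort(n_per_group = 1, R = 5, T = 30, noise_sd = 0.2, seed = 29)
  ts <- co$subjects[[1]]
  d <- exact_dmd(build_snapshots(ts))
  x0 <- ts$values[1, ]
  expect_equal(reconstruct_signal(d, x0, 0), x0, tolerance = 1e-10,
               ignore_attr = TRUE)
  # exact linear dynamics reconstruct every sampled time point
  sub <- small_linear_subject(R = 12, T = 50, freqs = c(0.03, 0.07), seed = 31)
  d2 <- exact_dmd(build_snapshots(sub))
  rec <- reconstruct_signal(d2, sub$values[1, ], (0:49) * 2)
  expect_lt(max(abs(rec - sub$values)), 1e-8)
  # noiseless in-band sinusoids: band-filtered modes carry all the energy
  # R must exceed the 18-dimensional oscillator state for exact recovery
  co3 <- small_sine_cohort(n_per_group = 1, R = 25, T = 60, seed = 37)
  ts3 <- co3$subjects[[1]]
  d3 <- exact_dmd(build_snapshots(ts3))
  rec3 <- reconstruct_signal(d3, ts3$values[1, ], (0:59) * 2,
                             subset = band_filter_modes(d3, c(0.01, 0.1)))
  rmse <- sqrt(mean((rec3 - ts3$values)^2))
  expect_lt(rmse, 1e-6)
  expect_error(reconstruct_signal(d3, ts3$values[1, ], 0,
                                  subset = structure(list(indices = integer(0), band = NULL),
                                                     class = "mode_subset")),
               "empty")
})

test_that("prediction extrapolates exact linear dynamics and returns per-horizon RMSE", {
  sub <- small_linear_subject(R = 12, T = 50, freqs = c(0.03, 0.07), seed = 41)
  ps <- predict_and_score(sub, n_train = 20)
  expect_length(ps$rmse, 30)
  expect_lt(max(ps$rmse), 1e-8)
  expect_false(any(ps$outlier))
  # shape contract: 5 held-out points give a 5-vector
  ps5 <- predict_and_score(sub, n_train = 45)
  expect_length(ps5$rmse, 5)
  expect_error(predict_and_score(sub, n_train = 50), "n_train")
  expect_error(predict_and_score(sub, n_train = 1), "n_train")
})

test_that("full-rank input yields T - 1 modes and a frequency-sorted spectrum", {
  co <- small_sine_cohort(n_per_group = 1, R = 40, T = 30, noise_sd = 0.4, seed = 43)
  d <- exact_dmd(build_snapshots(co$subjects[[1]]))
  # noise modes may land on the negative real axis; the count is recorded
  expect_gte(d$n_nyquist, 0)
  expect_equal(d$rank, 29L)
  expect_true(!is.unsorted(d$freqs))
  expect_true(all(d$freqs >= 0 & d$freqs <= 0.25 + 1e-12))
})

test_that("decomposition bundles round-trip key quantities through TSV/JSON", {
  sub <- small_linear_subject(R = 6, T = 30, freqs = 0.04, seed = 47)
  d <- exact_dmd(build_snapshots(sub))
  prefix <- file.path(withr::local_tempdir(), "dec")
  write_dmd(d, prefix)
  spec <- utils::read.delim(paste0(prefix, "_spectrum.tsv"))
  expect_equal(spec$freq_hz, d$freqs, tolerance = 1e-12)
  expect_equal(as.complex(spec$eigval), d$eigvals, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  expect_equal(meta$rank, d$rank)
})
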