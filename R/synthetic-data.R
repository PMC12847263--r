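#' Planted group effect specification
#'
#' Describes one planted abnormality: in the patient group, the oscillation
#' amplitude of one region inside one frequency band is scaled by
#' `1 + direction * relative_magnitude`.
#'
#' @param region_index 1-based region index.
#' @param band Length-2 numeric, frequency interval in Hz.
#' @param direction +1 (patient amplitude higher) or -1 (lower).
#' @param relative_magnitude Fractional amplitude change, > -1 and != 0.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region_index, band, direction, relative_magnitude) {
  assert_that(length(region_index) == 1 && region_index >= 1 &&
                region_index == round(region_index),
              "`region_index` must be a positive integer (1-based)")
  assert_that(length(band) == 2 && all(is.finite(band)) && band[1] < band[2] &&
                band[1] > 0, "`band` must be an increasing positive Hz interval")
  assert_that(direction %in% c(-1, 1), "`direction` must be +1 or -1")
  assert_that(is.finite(relative_magnitude) && relative_magnitude != 0 &&
                relative_magnitude > -1,
              "`relative_magnitude` must be finite, nonzero and > -1")
  structure(list(region_index = as.integer(region_index),
                 band = as.numeric(band),
                 direction = as.integer(direction),
                 relative_magnitude = as.numeric(relative_magnitude)),
            class = "effect_spec")
}

#' Synthetic cohort specification
#'
#' Defines the study conditions emulated by the sinusoid generator: cohort
#' size, grid dimensions, the oscillation frequency grid inside the infra-slow
#' band, per-region base amplitudes, additive noise, one out-of-band
#' component, the target signal range, and planted group effects.
#'
#' Defaults emulate a resting-state fMRI cohort: T = 140 samples at
#' dt = 2 s, R = 300 regions, oscillations concentrated in 0.01-0.1 Hz with
#' values concentrated in [-10, 10], plus a 0.15 Hz out-of-band component.
#'
#' @param n_per_group Subjects per group (patients and controls each).
#' @param R Number of regions.
#' @param T Number of time points (>= 2).
#' @param dt Sampling interval, seconds.
#' @param freq_grid In-band oscillation frequencies in Hz, all in
#'   (0, 1/(2 dt)]. Default: 9 frequencies evenly spaced in [0.015, 0.095] Hz.
#' @param base_amplitude Per-region nonnegative amplitude (scalar recycled).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param out_of_band_sd Amplitude of the out-of-band sinusoid at `oob_freq`.
#' @param oob_freq Frequency (Hz) of the out-of-band component.
#' @param signal_scale Length-2 target range most values should fall in.
#' @param effects List of [effect_spec()] objects planted in patients.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 68, R = 300, T = 140, dt = 2,
                        freq_grid = seq(0.015, 0.095, by = 0.01),
                        base_amplitude = 1.5, noise_sd = 0.5,
                        out_of_band_sd = 0.5, oob_freq = 0.15,
                        signal_scale = c(-10, 10), effects = list(),
                        seed = 1) {
  assert_that(n_per_group >= 1, "`n_per_group` must be >= 1")
  assert_that(T >= 2, "`T` must be >= 2")
  assert_that(dt > 0 && is.finite(dt), "`dt` must be positive")
  nyq <- 1 / (2 * dt)
  assert_that(all(is.finite(freq_grid)) && all(freq_grid > 0 & freq_grid <= nyq),
              "all `freq_grid` values must lie in (0, Nyquist]")
  base_amplitude <- rep_len(as.numeric(base_amplitude), R)
  assert_that(all(is.finite(base_amplitude)) && all(base_amplitude >= 0),
              "`base_amplitude` must be finite and nonnegative")
  assert_that(all(is.finite(c(noise_sd, out_of_band_sd, oob_freq))) &&
                noise_sd >= 0 && out_of_band_sd >= 0,
              "noise/out-of-band parameters must be finite and nonnegative")
  assert_that(length(signal_scale) == 2 && all(is.finite(signal_scale)) &&
                signal_scale[1] < signal_scale[2],
              "`signal_scale` must be an increasing finite interval")
  for (ef in effects) {
    assert_that(inherits(ef, "effect_spec"), "`effects` must be effect_spec objects")
    assert_that(ef$region_index <= R, "effect region_index out of range")
    covered <- any(freq_grid >= ef$band[1] & freq_grid <= ef$band[2])
    assert_that(covered, sprintf(
      "effect band [%g, %g] Hz contains no freq_grid oscillator", ef$band[1], ef$band[2]))
  }
  structure(list(n_per_group = as.integer(n_per_group), R = as.integer(R),
                 T = as.integer(T), dt = dt, freq_grid = as.numeric(freq_grid),
                 base_amplitude = base_amplitude, noise_sd = noise_sd,
                 out_of_band_sd = out_of_band_sd, oob_freq = oob_freq,
                 signal_scale = as.numeric(signal_scale), effects = effects,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

new_cohort <- function(subjects, labels, truth, spec = NULL) {
  stopifnot(length(subjects) == length(labels))
  structure(list(subjects = subjects, labels = as.integer(labels),
                 truth = truth, spec = spec),
            class = "dmd_cohort")
}

#' @export
print.dmd_cohort <- function(x, ...) {
  cat(sprintf("<dmd_cohort> %d subjects (%d patients / %d controls), %d x %d, dt = %g s\n",
              length(x$subjects), sum(x$labels == 1), sum(x$labels == 0),
              nrow(x$subjects[[1]]$values), ncol(x$subjects[[1]]$values),
              x$subjects[[1]]$dt))
  invisible(x)
}

#' Generate a sinusoid cohort with planted group effects
#'
#' Each subject's region-j series is a sum of sinusoids at the in-band
#' `freq_grid` frequencies with phases drawn i.i.d. uniform on [0, 2pi) per
#' subject/region/frequency, amplitude `base_amplitude[j]`, scaled by
#' `1 + direction * relative_magnitude` at frequencies inside an effect band
#' for patient-group subjects only, plus one out-of-band sinusoid of
#' amplitude `out_of_band_sd` at `oob_freq` and additive Gaussian noise of
#' standard deviation `noise_sd`. Controls come first (label 0), then
#' patients (label 1). Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `dmd_cohort`: list with `subjects` (list of [roi_timeseries()]),
#'   `labels` (0 = control, 1 = patient), `truth` (the planted effects) and
#'   the generating `spec`.
#' @examples
#' sp <- cohort_spec(n_per_group = 2, R = 4, T = 40, noise_sd = 0)
#' co <- generate_sinusoid_cohort(sp)
#' co$labels
#' @export
generate_sinusoid_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_sub <- 2L * spec$n_per_group
  labels <- rep(c(0L, 1L), each = spec$n_per_group)
  seeds <- derive_seeds(spec$seed, n_sub)
  tt <- (seq_len(spec$T) - 1) * spec$dt
  nf <- length(spec$freq_grid)
  region_labels <- sprintf("R%03d", seq_len(spec$R))

  # R x F amplitude matrices per group: controls use base amplitudes,
  # patients get effect bands rescaled.
  amp_ctrl <- matrix(spec$base_amplitude, spec$R, nf)
  amp_pat <- amp_ctrl
  for (ef in spec$effects) {
    hit <- spec$freq_grid >= ef$band[1] & spec$freq_grid <= ef$band[2]
    amp_pat[ef$region_index, hit] <-
      amp_pat[ef$region_index, hit] * (1 + ef$direction * ef$relative_magnitude)
  }

  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    set.seed(seeds[s])
    amp <- if (labels[s] == 1L) amp_pat else amp_ctrl
    x <- matrix(0, spec$T, spec$R)
    for (fi in seq_len(nf)) {
      theta <- runif(spec$R, 0, 2 * pi)
      x <- x + sin(outer(2 * pi * spec$freq_grid[fi] * tt, theta, `+`)) *
        rep(amp[, fi], each = spec$T)
    }
    if (spec$out_of_band_sd > 0) {
      theta <- runif(spec$R, 0, 2 * pi)
      x <- x + spec$out_of_band_sd *
        sin(outer(2 * pi * spec$oob_freq * tt, theta, `+`))
    }
    if (spec$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(spec$T * spec$R, sd = spec$noise_sd),
                      spec$T, spec$R)
    }
    subjects[[s]] <- roi_timeseries(x, dt = spec$dt, region_labels = region_labels)
  }
  new_cohort(subjects, labels, truth = spec$effects, spec = spec)
}

#' Generate a cohort from a planted linear dynamical system
#'
#' Each subject is a trajectory of `x[k+1] = A x[k]`, where `A` carries the
#' prescribed eigenvalues (complex ones in conjugate pairs) embedded in the
#' R-dimensional region space via a per-subject random orthonormal basis; the
#' initial state lies inside the invariant subspace, so the whole trajectory
#' exactly satisfies the linear dynamics. Each subject's series is rescaled so
#' its standard deviation equals one sixth of the `scale_to` range, keeping
#' values concentrated in that interval. Serves as the exact oracle for DMD
#' eigenvalue recovery and reconstruction.
#'
#' @param n_subjects Number of subjects.
#' @param R Number of regions (>= number of eigenvalues).
#' @param T Number of time points.
#' @param dt Sampling interval, seconds.
#' @param eigvals Complex (or real) eigenvalues, modulus <= 1; complex values
#'   must come in conjugate pairs so the output is real.
#' @param seed Integer master seed.
#' @param scale_to Length-2 target value range (default [-10, 10]).
#' @param noise_sd Standard deviation of additive Gaussian observation noise
#'   (default 0 = exact trajectories).
#' @return A `dmd_cohort` (labels split half 0 / half 1; no planted effects).
#' @examples
#' co <- generate_linear_system_cohort(2, R = 6, T = 30, dt = 2,
#'   eigvals = exp(c(1i, -1i) * 2 * pi * 0.05 * 2), seed = 1)
#' @export
generate_linear_system_cohort <- function(n_subjects, R, T, dt, eigvals, seed,
                                          scale_to = c(-10, 10), noise_sd = 0) {
  eigvals <- as.complex(eigvals)
  d <- length(eigvals)
  assert_that(R >= d, "`R` must be at least the number of eigenvalues")
  assert_that(T >= 2, "`T` must be >= 2")
  assert_that(all(Mod(eigvals) <= 1 + 1e-12),
              "eigenvalue moduli must be <= 1 (stable or marginal)")
  # Conjugate closure: every strictly complex eigenvalue needs its partner.
  cplx <- eigvals[abs(Im(eigvals)) > 1e-12]
  if (length(cplx) > 0) {
    pool <- cplx
    while (length(pool) > 0) {
      z <- pool[1]
      j <- which(Mod(pool - Conj(z)) < 1e-10)[1]
      if (is.na(j) || j == 1)
        stop("complex eigenvalues must be supplied in conjugate pairs", call. = FALSE)
      pool <- pool[-c(1, j)]
    }
  }
  # Real block-diagonal carrier of the spectrum.
  blocks <- list()
  used <- rep(FALSE, d)
  for (i in seq_len(d)) {
    if (used[i]) next
    z <- eigvals[i]
    if (abs(Im(z)) <= 1e-12) {
      blocks[[length(blocks) + 1]] <- matrix(Re(z), 1, 1)
      used[i] <- TRUE
    } else {
      j <- which(!used & Mod(eigvals - Conj(z)) < 1e-10 & seq_len(d) != i)[1]
      used[c(i, j)] <- TRUE
      a <- Re(z); b <- Im(z)
      blocks[[length(blocks) + 1]] <- matrix(c(a, b, -b, a), 2, 2)
    }
  }
  B <- matrix(0, d, d)
  at <- 1
  for (bl in blocks) {
    k <- nrow(bl)
    B[at:(at + k - 1), at:(at + k - 1)] <- bl
    at <- at + k
  }

  seeds <- derive_seeds(seed, n_subjects)
  region_labels <- sprintf("R%03d", seq_len(R))
  target_sd <- diff(scale_to) / 6
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(seeds[s])
    Q <- qr.Q(qr(matrix(stats::rnorm(R * d), R, d)))
    st <- stats::rnorm(d)
    x <- matrix(0, T, R)
    x[1, ] <- Q %*% st
    for (k in 2:T) {
      st <- B %*% st
      x[k, ] <- Q %*% st
    }
    sdx <- stats::sd(as.vector(x))
    if (sdx > 0) x <- x * (target_sd / sdx)
    if (noise_sd > 0) x <- x + matrix(stats::rnorm(T * R, sd = noise_sd), T, R)
    subjects[[s]] <- roi_timeseries(x, dt = dt, region_labels = region_labels)
  }
  labels <- rep(c(0L, 1L), length.out = n_subjects)
  new_cohort(subjects, sort(labels), truth = list(), spec = NULL)
}

#' Write a cohort to disk
#'
#' Writes one TSV per subject (header = region labels, rows = time points)
#' plus `manifest.json` holding labels, dt, planted truth and the seed.
#'
#' @param cohort A `dmd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dmd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("subject_%03d.tsv", seq_along(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    write_roi_tsv(cohort$subjects[[i]], file.path(dir, files[i]))
  }
  truth <- lapply(cohort$truth, function(ef) {
    list(region_index = ef$region_index, band = ef$band,
         direction = ef$direction, relative_magnitude = ef$relative_magnitude)
  })
  manifest <- list(files = files, labels = cohort$labels,
                   dt = cohort$subjects[[1]]$dt, truth = truth,
                   seed = if (!is.null(cohort$spec)) cohort$spec$seed else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing subject TSVs and `manifest.json`.
#' @return A `dmd_cohort`.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  subjects <- lapply(man$files, function(f) read_roi_tsv(file.path(dir, f), dt = man$dt))
  truth <- list()
  if (length(man$truth) > 0 && is.data.frame(man$truth)) {
    truth <- lapply(seq_len(nrow(man$truth)), function(i) {
      effect_spec(man$truth$region_index[i], unlist(man$truth$band[i]),
                  man$truth$direction[i], man$truth$relative_magnitude[i])
    })
  }
  new_cohort(subjects, man$labels, truth = truth, spec = NULL)
}
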