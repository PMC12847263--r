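#' Build the shifted snapshot pair
#'
#' Arranges a subject's time series as the two snapshot matrices used by DMD:
#' `X` holds time points 1..T-1 as columns (regions in rows) and `Xp` the same
#' series shifted one step forward in time (points 2..T).
#'
#' @param ts A [roi_timeseries()] object with T >= 2.
#' @return List of class `snapshot_pair` with `X`, `Xp` (both R x (T-1)),
#'   `dt`, `region_labels`.
#' @export
build_snapshots <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  T <- nrow(ts$values)
  assert_that(T >= 2, "need at least 2 time points (T >= 2)")
  M <- t(ts$values)                      # regions x time
  structure(list(X = M[, 1:(T - 1), drop = FALSE],
                 Xp = M[, 2:T, drop = FALSE],
                 dt = ts$dt, region_labels = ts$region_labels),
            class = "snapshot_pair")
}

#' Exact dynamic mode decomposition with scaled modes
#'
#' Decomposes the one-step evolution `Xp = A X` of a snapshot pair. The
#' algorithm: (1) thin SVD `X = U S V*`, discarding singular values below
#' `sv_tol` times the largest; (2) project the propagator,
#' `Atilde = U* Xp V S^-1`, and rescale it, `Ahat = S^-1/2 Atilde S^1/2`;
#' (3) eigendecompose `Ahat W_hat = W_hat Lambda` and scale the eigenvectors,
#' `W = S^1/2 W_hat`, so mode magnitudes are comparable across modes in the
#' manner of a power spectrum; (4) form the modes `Phi = Xp V S^-1 W`, one
#' column per eigenvalue.
#'
#' Modes are returned sorted by oscillation frequency (ascending), ties broken
#' by amplitude (descending) then by the sign of the eigenvalue's imaginary
#' part, so conjugate partners are adjacent and the ordering is reproducible.
#'
#' @param pair A [build_snapshots()] result.
#' @param dt Sampling interval in seconds (defaults to the pair's).
#' @param rank Optional hard rank truncation (<= retained singular values).
#' @param sv_tol Relative singular-value cutoff (default 1e-12): guards the
#'   `S^-1` inversion without truncating genuine signal directions.
#' @return An object of class `dmd` with `modes` (R x M complex), `eigvals`
#'   (length M complex), `freqs` (Hz), `amplitudes`, `singular_values`,
#'   `rank` (M), `dt`, `n_nyquist` (count of negative-real eigenvalues, whose
#'   frequency is pinned at Nyquist), `region_labels`.
#' @examples
#' ts <- roi_timeseries(cbind(2 ^ -(0:5)), dt = 1)
#' d <- exact_dmd(build_snapshots(ts))
#' d$eigvals  # 0.5: the generating map
#' @export
exact_dmd <- function(pair, dt = pair$dt, rank = NULL, sv_tol = 1e-12) {
  stopifnot(inherits(pair, "snapshot_pair"))
  sv <- svd(pair$X)
  if (sv$d[1] == 0) stop("all-zero input: no nonzero singular values", call. = FALSE)
  keep <- sv$d >= sv_tol * sv$d[1]
  if (!is.null(rank)) {
    assert_that(rank >= 1 && rank <= sum(keep),
                "`rank` must be between 1 and the number of retained singular values")
    keep <- seq_along(sv$d) <= rank & keep
  }
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  M <- length(d)
  Atilde <- crossprod(U, pair$Xp) %*% V %*% diag(1 / d, M)
  Ahat <- diag(1 / sqrt(d), M) %*% Atilde %*% diag(sqrt(d), M)
  eg <- eigen(Ahat)
  lam <- as.complex(eg$values)
  W <- diag(sqrt(d), M) %*% eg$vectors
  Phi <- (pair$Xp %*% V %*% diag(1 / d, M)) %*% W
  Phi <- matrix(as.complex(Phi), nrow = nrow(pair$Xp))

  # negative-real eigenvalues sit at the Nyquist frequency; recorded on the
  # object (n_nyquist) rather than warned per call — mode_frequencies() warns
  # when used directly
  freqs <- suppressWarnings(mode_frequencies(lam, dt))
  amps <- mode_amplitudes(Phi)
  ord <- order(freqs, -amps, -Im(lam))
  structure(list(modes = Phi[, ord, drop = FALSE], eigvals = lam[ord],
                 freqs = freqs[ord], amplitudes = amps[ord],
                 singular_values = d, rank = M, dt = dt,
                 n_nyquist = sum(Re(lam) < 0 & Im(lam) == 0),
                 region_labels = pair$region_labels),
            class = "dmd")
}

#' @export
print.dmd <- function(x, ...) {
  cat(sprintf("<dmd> %d modes over %d regions, dt = %g s; freq range [%.4g, %.4g] Hz\n",
              x$rank, nrow(x$modes), x$dt, min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Mode oscillation frequencies
#'
#' Converts discrete-time eigenvalues into oscillation frequencies,
#' `f_i = |Im(log(lambda_i)) / dt| / (2 pi)`, using the principal branch of
#' the logarithm. Frequencies fall in `[0, 1/(2 dt)]` (Nyquist). Eigenvalues
#' on the negative real axis map exactly to the Nyquist frequency and trigger
#' a warning, since their phase is ambiguous.
#'
#' @param eigvals Complex vector of nonzero eigenvalues.
#' @param dt Sampling interval in seconds.
#' @return Numeric vector of frequencies in Hz.
#' @export
mode_frequencies <- function(eigvals, dt) {
  assert_that(dt > 0, "`dt` must be positive")
  eigvals <- as.complex(eigvals)
  if (any(Mod(eigvals) == 0)) stop("zero eigenvalue: log undefined", call. = FALSE)
  neg_real <- Re(eigvals) < 0 & Im(eigvals) == 0
  if (any(neg_real)) {
    warning(sprintf("%d eigenvalue(s) on the negative real axis map to the Nyquist frequency",
                    sum(neg_real)))
  }
  abs(Im(log(eigvals)) / dt) / (2 * pi)
}

#' Mode amplitudes
#'
#' The amplitude of a mode is the squared 2-norm of its (complex) column:
#' with scaled modes this measures the energy the mode carries in the data,
#' analogous to a power spectrum.
#'
#' @param modes Complex R x M matrix of DMD modes (columns).
#' @return Nonnegative numeric vector of length M.
#' @export
mode_amplitudes <- function(modes) {
  modes <- as.matrix(modes)
  colSums(Mod(modes)^2)
}

#' Select modes inside a frequency band
#'
#' Returns the indices of modes whose frequencies fall in the closed interval
#' `band` (default the infra-slow 0.01-0.1 Hz band; modes outside it are
#' typically treated as physiological noise). Conjugate partners share a
#' frequency, so they are always kept or dropped together.
#'
#' @param dec A [exact_dmd()] decomposition.
#' @param band Length-2 numeric, Hz; must lie within [0, Nyquist].
#' @return Object of class `mode_subset`: list with sorted unique `indices`
#'   and the `band` that produced it. Empty result warns but is valid.
#' @export
band_filter_modes <- function(dec, band = c(0.01, 0.1)) {
  stopifnot(inherits(dec, "dmd"))
  nyq <- 1 / (2 * dec$dt)
  assert_that(length(band) == 2 && band[1] <= band[2] &&
                band[1] >= 0 && band[2] <= nyq + 1e-12,
              "`band` must lie within [0, Nyquist]")
  idx <- which(dec$freqs >= band[1] & dec$freqs <= band[2])
  if (length(idx) == 0) warning("no modes inside the requested band")
  structure(list(indices = sort(unique(idx)), band = as.numeric(band)),
            class = "mode_subset")
}

#' Full-mode subset
#'
#' @param dec A [exact_dmd()] decomposition.
#' @return A `mode_subset` covering all modes.
#' @export
all_modes <- function(dec) {
  structure(list(indices = seq_len(dec$rank), band = NULL), class = "mode_subset")
}

#' Reconstruct (or extrapolate) the signal from DMD modes
#'
#' Evaluates the explicit DMD signal model
#' `x(t) = Phi_s Lambda_s^(t/dt) b`, where `Phi_s`, `Lambda_s` are the modes
#' and eigenvalues restricted to `subset` and `b` is the least-squares
#' projection of the initial state onto those modes,
#' `b = pinv(Phi_s) x0` (Moore-Penrose pseudoinverse; the mode matrix is
#' rectangular, and a subset reconstruction re-projects `x0` rather than
#' zeroing entries of the full-mode coefficients). Fractional `t/dt` uses
#' principal-branch eigenvalue powers. The real part is returned; the largest
#' imaginary residual is attached as attribute `"imag_residual"`.
#'
#' @param dec A [exact_dmd()] decomposition.
#' @param x0 Length-R initial state (the signal at t = 0).
#' @param t Time(s) in seconds, >= 0; may be a vector.
#' @param subset Optional [band_filter_modes()] subset; default all modes.
#' @return Length-R numeric vector for scalar `t`, otherwise a
#'   `length(t)` x R matrix.
#' @export
reconstruct_signal <- function(dec, x0, t, subset = NULL) {
  stopifnot(inherits(dec, "dmd"))
  if (is.null(subset)) subset <- all_modes(dec)
  stopifnot(inherits(subset, "mode_subset"))
  assert_that(length(subset$indices) > 0, "empty mode subset: nothing to reconstruct from")
  assert_that(length(x0) == nrow(dec$modes), "`x0` must have one entry per region")
  assert_that(all(t >= 0), "`t` must be nonnegative")
  Phi <- dec$modes[, subset$indices, drop = FALSE]
  lam <- dec$eigvals[subset$indices]
  b <- pinv_solve(Phi, as.complex(x0))
  out <- matrix(NA_real_, length(t), nrow(Phi))
  imag_max <- 0
  for (i in seq_along(t)) {
    xc <- Phi %*% (principal_power(lam, t[i] / dec$dt) * b)
    imag_max <- max(imag_max, max(abs(Im(xc))))
    out[i, ] <- Re(xc)
  }
  if (length(t) == 1) out <- drop(out)
  attr(out, "imag_residual") <- imag_max
  out
}

#' Fit on a prefix, predict the held-out tail, and score
#'
#' Decomposes the first `n_train` time points of a subject, then extrapolates
#' via the DMD signal model from the last training state: horizon k is
#' predicted as `x(k dt)` with `x0` set to time point `n_train`. Returns the
#' root-mean-square error per horizon step against the held-out truth, plus
#' the flag marking horizons with RMSE > 1 (conventionally "poor prediction"
#' and excluded from curve summaries).
#'
#' @param ts A [roi_timeseries()] object.
#' @param n_train Number of leading time points to decompose (2 <= n_train < T).
#' @param band Optional Hz interval: predict from band-filtered modes only.
#' @param sv_tol Passed to [exact_dmd()].
#' @return List with `rmse` (length T - n_train), `horizons`, `outlier`
#'   (logical, RMSE > 1) and the fitted `dmd` object.
#' @export
predict_and_score <- function(ts, n_train, band = NULL, sv_tol = 1e-12) {
  stopifnot(inherits(ts, "roi_ts"))
  T <- nrow(ts$values)
  assert_that(n_train >= 2 && n_train < T, "`n_train` must satisfy 2 <= n_train < T")
  train <- roi_timeseries(ts$values[1:n_train, , drop = FALSE], dt = ts$dt,
                          region_labels = ts$region_labels)
  dec <- exact_dmd(build_snapshots(train), sv_tol = sv_tol)
  subset <- if (is.null(band)) all_modes(dec) else band_filter_modes(dec, band)
  horizons <- seq_len(T - n_train)
  x0 <- ts$values[n_train, ]
  pred <- reconstruct_signal(dec, x0, horizons * ts$dt, subset = subset)
  pred <- matrix(pred, nrow = length(horizons))
  truth <- ts$values[n_train + horizons, , drop = FALSE]
  rmse <- sqrt(rowMeans((pred - truth)^2))
  list(rmse = rmse, horizons = horizons, outlier = rmse > 1, dmd = dec)
}

#' Write a decomposition bundle
#'
#' Writes modes/eigenvalues/frequencies/amplitudes as TSV (complex values as
#' `"a+bi"` strings) plus a JSON metadata sidecar (dt, rank, singular values).
#'
#' @param dec A [exact_dmd()] decomposition.
#' @param prefix Output path prefix; writes `<prefix>_modes.tsv`,
#'   `<prefix>_spectrum.tsv`, `<prefix>_meta.json`.
#' @return `prefix`, invisibly.
#' @export
write_dmd <- function(dec, prefix) {
  stopifnot(inherits(dec, "dmd"))
  modes_chr <- matrix(format_complex(dec$modes), nrow = nrow(dec$modes))
  colnames(modes_chr) <- sprintf("mode%03d", seq_len(dec$rank))
  utils::write.table(data.frame(region = dec$region_labels, modes_chr,
                                check.names = FALSE),
                     paste0(prefix, "_modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spec <- data.frame(mode = seq_len(dec$rank),
                     eigval = format_complex(dec$eigvals),
                     freq_hz = dec$freqs, amplitude = dec$amplitudes)
  utils::write.table(spec, paste0(prefix, "_spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dt = dec$dt, rank = dec$rank,
                            singular_values = dec$singular_values),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
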