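#' Per-region mode power
#'
#' The power of mode i in region j is the squared magnitude of the mode's
#' entry at that region, `P_ij = |phi_ij|^2`: the strength of spatial pattern
#' i in region j. Row sums reproduce the mode amplitudes `P_i`.
#'
#' @param modes Complex R x M matrix of DMD modes (columns = modes).
#' @return M x R nonnegative matrix (rows = modes, columns = regions).
#' @export
region_mode_power <- function(modes) {
  modes <- as.matrix(modes)
  t(Mod(modes)^2)
}

#' Full-band mean-amplitude features
#'
#' The feature of region j is the mean over the retained modes of its
#' per-region power: `feature_j = sum_i P_ij / M`. This is the per-region
#' "mean amplitude" used as the classification feature.
#'
#' @param power M x R matrix from [region_mode_power()].
#' @param subset A `mode_subset` of retained modes (non-empty).
#' @return Length-R nonnegative vector.
#' @export
fullband_features <- function(power, subset) {
  stopifnot(inherits(subset, "mode_subset"))
  assert_that(length(subset$indices) > 0, "empty mode subset: mean over zero modes")
  colMeans(power[subset$indices, , drop = FALSE])
}

#' Equal-width partition of the infra-slow band
#'
#' Splits `band` (default [0.01, 0.1] Hz) into `k` equal-width sub-bands.
#' With k = 3 the edges are 0.01, 0.04, 0.07, 0.1 Hz.
#'
#' @param k Number of bands (>= 1).
#' @param band Length-2 Hz interval to partition.
#' @return Object of class `band_partition`: list with `edges` (k + 1
#'   increasing values) and `k`.
#' @export
make_band_partition <- function(k, band = c(0.01, 0.1)) {
  assert_that(length(k) == 1 && k >= 1 && k == round(k), "`k` must be a positive integer")
  structure(list(edges = seq(band[1], band[2], length.out = k + 1), k = as.integer(k)),
            class = "band_partition")
}

#' Sub-band spliced mean-amplitude features
#'
#' For each sub-band, averages the per-region power over the modes whose
#' frequency falls in that band (half-open `[low, high)` intervals, the last
#' band closed at its upper edge, so every mode lands in exactly one band),
#' then concatenates the per-band blocks in ascending frequency order (each
#' block = R regions). A band containing no modes contributes a zero block
#' and a warning.
#'
#' @param power M x R matrix from [region_mode_power()].
#' @param freqs Length-M frequency vector from the same decomposition.
#' @param partition A [make_band_partition()].
#' @return Length R*k nonnegative vector; attribute `"band_counts"` holds the
#'   number of modes per band.
#' @export
subband_features <- function(power, freqs, partition) {
  stopifnot(inherits(partition, "band_partition"))
  assert_that(length(freqs) == nrow(power),
              "`freqs` must have one entry per mode (row of `power`)")
  R <- ncol(power)
  k <- partition$k
  e <- partition$edges
  out <- numeric(R * k)
  counts <- integer(k)
  for (b in seq_len(k)) {
    hi_closed <- b == k
    idx <- which(freqs >= e[b] & (if (hi_closed) freqs <= e[b + 1] else freqs < e[b + 1]))
    counts[b] <- length(idx)
    if (length(idx) == 0) {
      warning(sprintf("band %d [%g, %g%s Hz contains no modes; zero block emitted",
                      b, e[b], e[b + 1], if (hi_closed) "]" else ")"))
      next
    }
    out[(b - 1) * R + seq_len(R)] <- colMeans(power[idx, , drop = FALSE])
  }
  attr(out, "band_counts") <- counts
  out
}

#' Cohort-level feature table
#'
#' Decomposes every subject with exact DMD, retains modes inside `band`, and
#' assembles the per-region mean-amplitude features into an N x p table
#' (p = R for full-band, R*k for sub-band splicing).
#'
#' @param cohort A `dmd_cohort`.
#' @param mode `"full"` (one feature per region) or `"subband"` (k blocks).
#' @param k Number of sub-bands (used when `mode = "subband"`).
#' @param band Hz interval of retained modes (default [0.01, 0.1]).
#' @param sv_tol Passed to [exact_dmd()].
#' @return Object of class `feature_table`: `values` (N x p), `feature_names`,
#'   `labels`, and `feature_info` (data frame with region/band per column).
#' @export
assemble_feature_table <- function(cohort, mode = c("full", "subband"), k = 3,
                                   band = c(0.01, 0.1), sv_tol = 1e-12) {
  stopifnot(inherits(cohort, "dmd_cohort"))
  mode <- match.arg(mode)
  N <- length(cohort$subjects)
  assert_that(N >= 1, "empty cohort")
  dims <- vapply(cohort$subjects, function(s) dim(s$values), integer(2))
  dts <- vapply(cohort$subjects, function(s) s$dt, numeric(1))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]) &&
                all(dts == dts[1]),
              "all subjects must share T, R and dt")
  R <- dims[2, 1]
  region_labels <- cohort$subjects[[1]]$region_labels
  partition <- if (mode == "subband") make_band_partition(k, band) else NULL
  p <- if (mode == "full") R else R * k
  values <- matrix(NA_real_, N, p)
  for (i in seq_len(N)) {
    dec <- exact_dmd(build_snapshots(cohort$subjects[[i]]), sv_tol = sv_tol)
    keep <- band_filter_modes(dec, band)
    power <- region_mode_power(dec$modes)
    if (mode == "full") {
      values[i, ] <- fullband_features(power, keep)
    } else {
      values[i, ] <- subband_features(power[keep$indices, , drop = FALSE],
                                      dec$freqs[keep$indices], partition)
    }
  }
  if (mode == "full") {
    feature_names <- region_labels
    info <- data.frame(region = region_labels, band_label = "full",
                       band_lo = band[1], band_hi = band[2],
                       stringsAsFactors = FALSE)
  } else {
    e <- partition$edges
    band_label <- sprintf("b%d", seq_len(k))
    feature_names <- as.vector(t(outer(band_label, region_labels, paste, sep = ":")))
    info <- data.frame(region = rep(region_labels, times = k),
                       band_label = rep(band_label, each = R),
                       band_lo = rep(e[-(k + 1)], each = R),
                       band_hi = rep(e[-1], each = R),
                       stringsAsFactors = FALSE)
  }
  structure(list(values = values, feature_names = feature_names,
                 labels = cohort$labels, feature_info = info,
                 subject_ids = sprintf("S%03d", seq_len(N))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%d patients / %d controls)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Write / read a feature table as TSV
#'
#' One row per subject: subject id, group label, then feature columns.
#'
#' @param table A `feature_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject = table$subject_ids, label = table$labels,
                   table$values, check.names = FALSE)
  names(df)[-(1:2)] <- table$feature_names
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  structure(list(values = unname(vals), feature_names = colnames(vals),
                 labels = as.integer(df$label), feature_info = NULL,
                 subject_ids = as.character(df$subject)),
            class = "feature_table")
}

#' Construct a feature table directly
#'
#' For features computed externally or assembled by hand (tests, custom
#' pipelines). [assemble_feature_table()] is the usual entry point.
#'
#' @param values N x p numeric matrix.
#' @param labels Length-N binary 0/1 group labels (patient = 1).
#' @param feature_names Optional unique column names.
#' @param feature_info Optional per-feature data frame (region, band).
#' @return A `feature_table`.
#' @export
feature_table <- function(values, labels, feature_names = NULL, feature_info = NULL) {
  values <- as.matrix(values)
  assert_that(nrow(values) == length(labels), "one label per row required")
  if (is.null(feature_names)) feature_names <- sprintf("F%03d", seq_len(ncol(values)))
  assert_that(!anyDuplicated(feature_names), "feature names must be unique")
  structure(list(values = values, feature_names = feature_names,
                 labels = as.integer(labels), feature_info = feature_info,
                 subject_ids = sprintf("S%03d", seq_len(nrow(values)))),
            class = "feature_table")
}
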