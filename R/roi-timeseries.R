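#' ROI time-series container
#'
#' A single subject's regions-of-interest time series: a numeric matrix with
#' time points in rows and regions in columns, plus the sampling interval
#' (the fMRI repetition time, in seconds) and region labels.
#'
#' @param values Numeric T x R matrix (T time points, R regions); all values
#'   must be finite and T >= 2.
#' @param dt Sampling interval in seconds (> 0). Resting-state fMRI is
#'   typically sampled every 2 s.
#' @param region_labels Optional character vector of length R; defaults to
#'   `"R001"`, `"R002"`, ...
#' @return An object of class `roi_ts` with elements `values`, `dt`,
#'   `region_labels`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(20), 10, 2), dt = 2)
#' dim(ts$values)
#' @export
roi_timeseries <- function(values, dt, region_labels = NULL) {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "`values` must be a numeric matrix")
  assert_that(nrow(values) >= 2, "need at least 2 time points (T >= 2)")
  assert_that(all(is.finite(values)), "`values` must be finite")
  assert_that(is.numeric(dt) && length(dt) == 1 && is.finite(dt) && dt > 0,
              "`dt` must be a positive scalar (seconds)")
  R <- ncol(values)
  if (is.null(region_labels)) region_labels <- sprintf("R%03d", seq_len(R))
  assert_that(length(region_labels) == R,
              "`region_labels` must have one entry per region")
  structure(list(values = values, dt = dt,
                 region_labels = as.character(region_labels)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %d time points x %d regions, dt = %g s\n",
              nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

#' Read an ROI time-series TSV
#'
#' Expects a tab-separated file whose header row holds region labels and whose
#' body is numeric, one row per time point.
#'
#' @param path File path.
#' @param dt Sampling interval in seconds to attach (not stored in the TSV).
#' @return A [roi_timeseries()] object.
#' @seealso [write_roi_tsv()]
#' @export
read_roi_tsv <- function(path, dt = 2) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  assert_that(nrow(df) >= 2, "need at least 2 time points (T >= 2)")
  vals <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row %d, column %d ('%s') in %s",
                   bad[1], j, df[bad[1], j], path), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value at row %d, column %d in %s",
                   which(is.na(v))[1], j, path), call. = FALSE)
    }
    vals[, j] <- v
  }
  roi_timeseries(vals, dt = dt, region_labels = colnames(df))
}

#' Write an ROI time-series TSV
#'
#' @param ts A [roi_timeseries()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  df <- as.data.frame(ts$values)
  names(df) <- ts$region_labels
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Schaefer-style default network labels
#'
#' Assigns each region to one of the seven canonical resting-state networks
#' (visual, somatomotor, dorsal attention, salience/ventral attention, limbic,
#' control, default mode) in contiguous blocks, mimicking the ordering of a
#' Schaefer-style parcellation. Used when no region-to-network table is given.
#'
#' @param R Number of regions.
#' @return Character vector of length `R`.
#' @export
default_network_labels <- function(R) {
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  nets[pmin(length(nets), 1L + ((seq_len(R) - 1L) * length(nets)) %/% R)]
}
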