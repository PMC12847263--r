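#' Functional connectivity matrix
#'
#' Pearson correlation between every pair of region time courses. A constant
#' region series has no defined correlation: its row and column are set to 0
#' (diagonal kept at 1) with a warning.
#'
#' @param ts A [roi_timeseries()] with T >= 3.
#' @return Object of class `connectivity_matrix`: list with `values`
#'   (R x R symmetric, unit diagonal), `kind = "FC"`, `region_labels`.
#' @export
functional_connectivity <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  assert_that(nrow(ts$values) >= 3, "need at least 3 time points for correlation")
  sds <- apply(ts$values, 2, stats::sd)
  const <- sds == 0
  vals <- suppressWarnings(stats::cor(ts$values))
  if (any(const)) {
    warning(sprintf("%d constant region series: correlations set to 0", sum(const)))
    vals[const, ] <- 0
    vals[, const] <- 0
  }
  diag(vals) <- 1
  structure(list(values = vals, kind = "FC", region_labels = ts$region_labels),
            class = "connectivity_matrix")
}

#' Mode-sequence correlation matrix (phiC)
#'
#' Treats row j of the subset-restricted mode matrix (one complex entry per
#' retained mode) as region j's "mode sequence" and correlates region pairs
#' with the real part of the conjugate (uncentered) cosine similarity:
#' `r_jk = Re(sum_i phi_ji conj(phi_ki)) / (||phi_j|| ||phi_k||)`.
#' No mean is removed across modes: for real-valued signals the time-domain
#' mean corresponds to a zero-frequency mode, which band filtering already
#' excludes, so the uncentered similarity is the mode-space analogue of the
#' Pearson correlation of the time courses. Zero rows are handled like
#' constant series in [functional_connectivity()].
#'
#' @param dec A [exact_dmd()] decomposition.
#' @param subset A `mode_subset` with at least 2 modes.
#' @return A `connectivity_matrix` with `kind = "phiC"`.
#' @export
mode_sequence_correlation <- function(dec, subset) {
  stopifnot(inherits(dec, "dmd"), inherits(subset, "mode_subset"))
  assert_that(length(subset$indices) >= 2, "need at least 2 modes for phiC")
  Z <- dec$modes[, subset$indices, drop = FALSE]
  gram <- Z %*% Conj(t(Z))
  nrm <- sqrt(Re(diag(gram)))
  zero <- nrm == 0
  nrm[zero] <- 1
  vals <- Re(gram) / outer(nrm, nrm)
  if (any(zero)) {
    warning(sprintf("%d zero-variance mode row(s): correlations set to 0", sum(zero)))
    vals[zero, ] <- 0
    vals[, zero] <- 0
  }
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  structure(list(values = vals, kind = "phiC", region_labels = dec$region_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d x %d\n", x$kind,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Compare two connectivity matrices
#'
#' Pearson correlation and RMSE of the matched strictly-upper-triangle
#' entries (diagonal excluded).
#'
#' @param a,b `connectivity_matrix` objects with equal shapes.
#' @return List with `pearson_r`, `rmse`, `n_pairs` (= R(R-1)/2).
#' @export
compare_connectivity <- function(a, b) {
  stopifnot(inherits(a, "connectivity_matrix"), inherits(b, "connectivity_matrix"))
  assert_that(all(dim(a$values) == dim(b$values)), "shape mismatch")
  ut <- upper.tri(a$values)
  va <- a$values[ut]
  vb <- b$values[ut]
  list(pearson_r = stats::cor(va, vb),
       rmse = sqrt(mean((va - vb)^2)),
       n_pairs = length(va))
}

#' Write a connectivity matrix as TSV
#'
#' Region labels as header row and first column.
#'
#' @param cm A `connectivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(region = cm$region_labels, cm$values, check.names = FALSE)
  names(df)[-1] <- cm$region_labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
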