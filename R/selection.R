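#' LASSO selection configuration
#'
#' @param gamma L1 regularization strength (> 0). With standardized features
#'   and 0/1 labels this is the soft-threshold the (univariate) sample
#'   covariance must exceed for a feature to enter; default 0.2.
#' @param n_folds Cross-validation folds used for the per-run validation MSE
#'   (default 10).
#' @param n_repeats Number of repeated LASSO runs whose selections are
#'   intersected (default 1000).
#' @param standardize Standardize features to zero mean / unit (population)
#'   variance before fitting (default TRUE); labels stay 0/1.
#' @param seed Integer seed controlling fold shuffling across runs.
#' @return Object of class `lasso_config`.
#' @export
lasso_config <- function(gamma = 0.2, n_folds = 10, n_repeats = 1000,
                         standardize = TRUE, seed = 1) {
  assert_that(gamma > 0, "`gamma` must be positive")
  assert_that(n_folds >= 2, "`n_folds` must be >= 2")
  assert_that(n_repeats >= 1, "`n_repeats` must be >= 1")
  structure(list(gamma = gamma, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "lasso_config")
}

# Standardize columns to mean 0, population (1/N) variance 1.
# Constant columns are dropped (coefficients forced to zero) with a warning.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  const <- sdv == 0
  if (any(const)) warning(sprintf("%d constant feature column(s) dropped", sum(const)))
  xs <- sweep(x, 2, mu)
  xs[, !const] <- sweep(xs[, !const, drop = FALSE], 2, sdv[!const], `/`)
  xs[, const] <- 0
  list(x = xs, const = const, mu = mu, sd = sdv)
}

glmnet_at_gamma <- function(x, y, gamma) {
  # glmnet requires >= 2 columns; pad single-feature problems with a zero
  # column (coefficient provably zero) and strip it afterwards
  pad <- ncol(x) == 1
  if (pad) x <- cbind(x, 0)
  path <- gamma * c(16, 8, 4, 2, 1)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1, lambda = path,
                        standardize = FALSE, intercept = TRUE, thresh = 1e-12)
  beta <- as.numeric(stats::coef(fit, s = gamma))[-1]
  if (pad) beta <- beta[1]
  beta
}

#' Single LASSO fit with fold-based validation
#'
#' Fits the L1-penalized regression of the 0/1 group label on the features,
#' minimizing `||y - X b||^2 / (2N) + gamma ||b||_1` at fixed `gamma`
#' (coordinate descent via glmnet). Folds are shuffled by `seed` and used to
#' compute a held-out validation MSE at `gamma`; the returned coefficients are
#' fit on the full data. "Selected" features are those with |coefficient|
#' above a 1e-10 floor (guarding solver float dust).
#'
#' @param table A `feature_table`.
#' @param config A [lasso_config()].
#' @param seed Seed for this run's fold shuffle (default `config$seed`).
#' @return List with `coefficients` (length p, on the standardized scale),
#'   `selected` (integer indices), `cv_mse`.
#' @export
lasso_fit <- function(table, config, seed = config$seed) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "lasso_config"))
  y <- as.numeric(table$labels)
  assert_that(all(y %in% c(0, 1)), "labels must be binary 0/1")
  N <- length(y)
  assert_that(N >= config$n_folds, "need at least `n_folds` subjects")
  x <- table$values
  if (config$standardize) {
    st <- standardize_columns(x)
    x <- st$x
  }
  set.seed(seed)
  folds <- sample(rep(seq_len(config$n_folds), length.out = N))
  cv_err <- numeric(config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    beta_f <- glmnet_at_gamma(x[tr, , drop = FALSE], y[tr], config$gamma)
    mu_f <- mean(y[tr])
    pred <- x[!tr, , drop = FALSE] %*% beta_f +
      (mu_f - sum(colMeans(x[tr, , drop = FALSE]) * beta_f))
    cv_err[f] <- mean((y[!tr] - pred)^2)
  }
  beta <- glmnet_at_gamma(x, y, config$gamma)
  selected <- which(abs(beta) > 1e-10)
  list(coefficients = beta, selected = selected, cv_mse = mean(cv_err))
}

#' Repeated LASSO selection and intersection
#'
#' Runs [lasso_fit()] `n_repeats` times with independently shuffled fold
#' assignments and intersects the selected feature sets: only features with a
#' nonzero coefficient in every run survive. An empty intersection is a valid
#' outcome (warning, not error).
#'
#' @param table A `feature_table`.
#' @param config A [lasso_config()].
#' @return Object of class `selection_result` with `per_run_selected` (list of
#'   index vectors), `intersection`, `per_run_coefficients`
#'   (n_repeats x p matrix), `mean_coefficients` over the intersection,
#'   `selection_frequency`, plus empty slots for the permutation stage
#'   (`perm_pvalues`, `abnormal`, `alpha`) filled by [call_abnormal_regions()].
#' @export
repeated_lasso_selection <- function(table, config) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "lasso_config"))
  p <- ncol(table$values)
  run_seeds <- derive_seeds(config$seed, config$n_repeats)
  coefs <- matrix(0, config$n_repeats, p)
  per_run <- vector("list", config$n_repeats)
  cv_mse <- numeric(config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    fit <- lasso_fit(table, config, seed = run_seeds[r])
    coefs[r, ] <- fit$coefficients
    per_run[[r]] <- fit$selected
    cv_mse[r] <- fit$cv_mse
  }
  intersection <- Reduce(intersect, per_run)
  if (length(intersection) == 0) warning("empty selection intersection")
  intersection <- sort(intersection)
  structure(list(per_run_selected = per_run,
                 intersection = intersection,
                 per_run_coefficients = coefs,
                 mean_coefficients = mean_coefficients(coefs, intersection),
                 selection_frequency = colMeans(abs(coefs) > 1e-10),
                 cv_mse = cv_mse,
                 perm_pvalues = NULL, abnormal = NULL, alpha = NULL,
                 feature_names = table$feature_names),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d runs, intersection of %d feature(s)%s\n",
              length(x$per_run_selected), length(x$intersection),
              if (!is.null(x$abnormal)) sprintf(", %d abnormal at alpha = %g",
                                                length(x$abnormal), x$alpha) else ""))
  invisible(x)
}

#' Mean coefficients over intersected features
#'
#' Arithmetic mean of each intersected feature's coefficient across runs.
#' With patients labeled 1 and controls 0, a positive mean coefficient means
#' the patient group's mean amplitude is higher in that feature, a negative
#' one lower; the magnitude ranks the deviation's severity.
#'
#' @param per_run_coefs n_runs x p matrix (or list of coefficient vectors).
#' @param intersection Integer feature indices.
#' @return Named numeric vector, one entry per intersected feature.
#' @export
mean_coefficients <- function(per_run_coefs, intersection) {
  if (is.list(per_run_coefs)) per_run_coefs <- do.call(rbind, per_run_coefs)
  out <- colMeans(per_run_coefs[, intersection, drop = FALSE])
  names(out) <- as.character(intersection)
  out
}

#' Permutation test for a group difference in one feature
#'
#' Two-sided test of the absolute difference of group means against the null
#' distribution obtained by permuting the group labels B times. The p-value
#' uses the add-one estimator `p = (#{permuted >= observed} + 1) / (B + 1)`,
#' so it is bounded in [1/(B+1), 1]; a constant feature yields p = 1.
#'
#' @param feature_values Numeric vector, one value per subject.
#' @param labels Binary 0/1 group labels (both groups non-empty).
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
group_difference_permutation_test <- function(feature_values, labels, B = 1000,
                                              seed = 1) {
  labels <- as.integer(labels)
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  assert_that(any(labels == 0L) && any(labels == 1L), "both groups must be non-empty")
  assert_that(B >= 1, "`B` must be >= 1")
  obs <- abs(mean(feature_values[labels == 1L]) - mean(feature_values[labels == 0L]))
  set.seed(seed)
  n1 <- sum(labels == 1L)
  total <- sum(feature_values)
  n0 <- sum(labels == 0L)
  ge <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(length(labels), n1)
    m1 <- sum(feature_values[idx]) / n1
    m0 <- (total - sum(feature_values[idx])) / n0
    if (abs(m1 - m0) >= obs - 1e-15) ge <- ge + 1L
  }
  (ge + 1) / (B + 1)
}

#' Call abnormal regions from an intersection
#'
#' Completes a [repeated_lasso_selection()] result: runs the group-difference
#' permutation test on every intersected feature and calls "abnormal" those
#' with p < `alpha`. Returns both the completed `selection_result` and a
#' per-feature report annotated with region, band and network labels.
#'
#' @param result A `selection_result`.
#' @param table The `feature_table` the selection was computed on.
#' @param alpha Significance level (default 0.05).
#' @param B Permutations per feature (default 1000).
#' @param seed Integer seed.
#' @param region_networks Optional named character vector mapping region
#'   labels to network names; defaults to [default_network_labels()] applied
#'   to the distinct regions.
#' @return The completed `selection_result`, with `perm_pvalues`, `abnormal`,
#'   `alpha` filled and a `report` data frame (feature, region, band,
#'   network, mean coefficient, p-value, abnormal flag).
#' @export
call_abnormal_regions <- function(result, table, alpha = 0.05, B = 1000,
                                  seed = 1, region_networks = NULL) {
  stopifnot(inherits(result, "selection_result"), inherits(table, "feature_table"))
  idx <- result$intersection
  seeds <- derive_seeds(seed, max(1L, length(idx)))
  pvals <- numeric(length(idx))
  for (i in seq_along(idx)) {
    pvals[i] <- group_difference_permutation_test(table$values[, idx[i]],
                                                  table$labels, B = B,
                                                  seed = seeds[i])
  }
  abnormal <- idx[pvals < alpha]
  info <- table$feature_info
  if (is.null(info)) {
    info <- data.frame(region = table$feature_names, band_label = "full",
                       stringsAsFactors = FALSE)
  }
  regions <- info$region[idx]
  if (is.null(region_networks)) {
    all_regions <- unique(info$region)
    region_networks <- stats::setNames(default_network_labels(length(all_regions)),
                                       all_regions)
  }
  report <- data.frame(
    feature = idx,
    feature_name = table$feature_names[idx],
    region = regions,
    band = info$band_label[idx],
    network = unname(region_networks[regions]),
    mean_coefficient = unname(result$mean_coefficients[as.character(idx)]),
    p_value = pvals,
    abnormal = pvals < alpha,
    stringsAsFactors = FALSE)
  result$perm_pvalues <- stats::setNames(pvals, as.character(idx))
  result$abnormal <- abnormal
  result$alpha <- alpha
  result$report <- report
  result
}

#' Write a selection result
#'
#' Writes the selection summary as JSON (selection frequencies, intersection,
#' mean coefficients, p-values) and the abnormal-region report as TSV.
#'
#' @param result A completed `selection_result`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_selection_result <- function(result, prefix) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(
    n_runs = length(result$per_run_selected),
    selection_frequency = result$selection_frequency,
    intersection = result$intersection,
    mean_coefficients = as.list(result$mean_coefficients),
    perm_pvalues = as.list(result$perm_pvalues %||% numeric(0)),
    alpha = result$alpha
  ), paste0(prefix, "_selection.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$report)) {
    utils::write.table(result$report, paste0(prefix, "_abnormal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
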