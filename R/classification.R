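#' Confusion-matrix classification metrics
#'
#' Accuracy, precision, recall, F1 and specificity from the four confusion
#' counts, with the patient group as the positive class. Ratios with a zero
#' denominator are reported as 0 and flagged in the `"undefined"` attribute.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts, at least one positive.
#' @return Named numeric vector of the five metrics with attribute
#'   `"undefined"` naming any degenerate ratios.
#' @export
classification_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  assert_that(all(counts >= 0), "counts must be nonnegative")
  assert_that(sum(counts) >= 1, "at least one count must be positive")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { flags <<- c(flags, name); 0 } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) { flags <- c(flags, "f1"); 0 } else {
    2 * precision * recall / (precision + recall)
  }
  out <- c(accuracy = (tp + tn) / sum(counts), precision = precision,
           recall = recall, f1 = f1,
           specificity = safe(tn, tn + fp, "specificity"))
  attr(out, "undefined") <- flags
  out
}

# Stratified fold assignment: each class spread evenly across folds.
stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    out[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  out
}

#' Cross-validated linear SVM benchmark
#'
#' Evaluates a feature table with a linear support vector machine under
#' `rounds` repetitions of stratified `folds`-fold cross-validation
#' (3 x 10 = 30 metric rows by default). Per fold, features are standardized
#' on the training split only. Variants:
#' \describe{
#'   \item{plain}{all features (the un-selected benchmark);}
#'   \item{per_fold_lasso}{LASSO selection on the training split only, then
#'     classification on the selected features (falls back to all features
#'     with a warning if the selection is empty);}
#'   \item{fixed_subset}{restrict to a given feature subset (e.g. the
#'     repeated-LASSO intersection). Note the subset is typically computed on
#'     all data, so its CV estimate carries the corresponding optimistic
#'     selection bias;}
#'   \item{chance}{permute the training labels before fitting (empirical
#'     chance level).}
#' }
#' The fold assignments are driven by `seed` alone, so different variants run
#' with the same seed share identical train/test divisions.
#'
#' @param table A `feature_table` with binary labels.
#' @param rounds CV repetitions (default 3).
#' @param folds Folds per round (default 10).
#' @param variant One of `"plain"`, `"per_fold_lasso"`, `"fixed_subset"`,
#'   `"chance"`.
#' @param subset Integer feature indices (required for `fixed_subset`).
#' @param gamma LASSO strength for `per_fold_lasso` (default 0.2).
#' @param C SVM cost parameter (default 1).
#' @param seed Integer seed (folds; and label perturbation for `chance`).
#' @param name Optional feature-set name stored with the result.
#' @return Object of class `metric_set`: data frame with `round`, `fold` and
#'   the five metrics; attribute `"feature_set_name"`.
#' @export
cross_validated_svm <- function(table, rounds = 3, folds = 10,
                                variant = c("plain", "per_fold_lasso",
                                            "fixed_subset", "chance"),
                                subset = NULL, gamma = 0.2, C = 1, seed = 1,
                                name = NULL) {
  stopifnot(inherits(table, "feature_table"))
  variant <- match.arg(variant)
  y <- as.integer(table$labels)
  assert_that(all(y %in% c(0L, 1L)), "labels must be binary 0/1")
  N <- length(y)
  assert_that(N >= folds, "need at least `folds` subjects")
  if (variant == "fixed_subset") {
    assert_that(!is.null(subset) && length(subset) > 0,
                "`fixed_subset` needs a non-empty `subset`")
  }
  fold_seeds <- derive_seeds(seed, rounds)
  perturb_seeds <- derive_seeds(seed + 1L, rounds * folds)
  rows <- vector("list", rounds * folds)
  ri <- 0L
  for (rd in seq_len(rounds)) {
    set.seed(fold_seeds[rd])
    fold_id <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      ri <- ri + 1L
      tr <- fold_id != f
      if (length(unique(y[!tr])) < 1 || length(unique(y[tr])) < 2)
        stop("degenerate fold: one class only", call. = FALSE)
      xtr <- table$values[tr, , drop = FALSE]
      xte <- table$values[!tr, , drop = FALSE]
      ytr <- y[tr]
      if (variant == "chance") {
        set.seed(perturb_seeds[ri])
        ytr <- sample(ytr)
      }
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, `/`)
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, `/`)
      cols <- switch(variant,
        plain = , chance = seq_len(ncol(xtr)),
        fixed_subset = subset,
        per_fold_lasso = {
          beta <- glmnet_at_gamma(xtr, as.numeric(ytr), gamma)
          sel <- which(abs(beta) > 1e-10)
          if (length(sel) == 0) {
            warning("per-fold LASSO selected no features; using all")
            sel <- seq_len(ncol(xtr))
          }
          sel
        })
      fit <- e1071::svm(xtr[, cols, drop = FALSE], factor(ytr, levels = c(0, 1)),
                        kernel = "linear", cost = C, scale = FALSE)
      pred <- stats::predict(fit, xte[, cols, drop = FALSE])
      yte <- y[!tr]
      tp <- sum(pred == "1" & yte == 1L)
      fp <- sum(pred == "1" & yte == 0L)
      fn <- sum(pred == "0" & yte == 1L)
      tn <- sum(pred == "0" & yte == 0L)
      m <- classification_metrics(tp, fp, fn, tn)
      rows[[ri]] <- data.frame(round = rd, fold = f, t(m))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "feature_set_name") <- name %||% variant
  class(out) <- c("metric_set", class(out))
  out
}

#' Permutation comparison of two metric distributions
#'
#' For each of the five metrics, tests the absolute difference of means
#' between two metric sets against the null obtained by pooling the values
#' and randomly reassigning them to two groups of the original sizes
#' (unpaired permutation), with the add-one p-value estimator.
#'
#' @param a,b `metric_set` objects with equal row counts.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `comparison_result`: data frame with one row per
#'   metric (`metric`, `mean_a`, `mean_b`, `p_value`); attribute `"B"`.
#' @export
compare_feature_sets_permutation <- function(a, b, B = 1000, seed = 1) {
  metrics <- c("accuracy", "precision", "recall", "f1", "specificity")
  assert_that(nrow(a) == nrow(b), "metric sets must have equal row counts")
  set.seed(seed)
  n <- nrow(a)
  rows <- lapply(metrics, function(m) {
    va <- a[[m]]
    vb <- b[[m]]
    obs <- abs(mean(va) - mean(vb))
    pooled <- c(va, vb)
    ge <- 0L
    for (i in seq_len(B)) {
      idx <- sample.int(2 * n, n)
      stat <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
      if (stat >= obs - 1e-15) ge <- ge + 1L
    }
    data.frame(metric = m, mean_a = mean(va), mean_b = mean(vb),
               p_value = (ge + 1) / (B + 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "B") <- B
  attr(out, "names_ab") <- c(attr(a, "feature_set_name") %||% "a",
                             attr(b, "feature_set_name") %||% "b")
  class(out) <- c("comparison_result", class(out))
  out
}
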