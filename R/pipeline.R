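#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default.
#'
#' @param dt Sampling interval, seconds (default 2).
#' @param band Retained frequency band in Hz (default [0.01, 0.1]).
#' @param k Number of sub-bands for the spliced features (default 3).
#' @param gamma LASSO strength (default 0.2).
#' @param n_repeats Repeated LASSO runs (default 1000).
#' @param B Permutations for the abnormal-region and metric tests (default 1000).
#' @param alpha Significance level for abnormal calls (default 0.05).
#' @param rounds,folds SVM cross-validation design (default 3 x 10).
#' @param C Linear SVM cost (default 1).
#' @param n_folds LASSO validation folds (default 10).
#' @param seed Master seed for every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(dt = 2, band = c(0.01, 0.1), k = 3, gamma = 0.2,
                            n_repeats = 1000, B = 1000, alpha = 0.05,
                            rounds = 3, folds = 10, C = 1, n_folds = 10,
                            seed = 1) {
  assert_that(all(c(k, n_repeats, B, rounds, folds, n_folds) >= 1),
              "all counts must be >= 1")
  assert_that(band[1] >= 0 && band[2] <= 1 / (2 * dt) && band[1] < band[2],
              "`band` must lie within (0, Nyquist]")
  structure(list(dt = dt, band = as.numeric(band), k = as.integer(k),
                 gamma = gamma, n_repeats = as.integer(n_repeats),
                 B = as.integer(B), alpha = alpha, rounds = as.integer(rounds),
                 folds = as.integer(folds), C = C,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates: per-subject exact DMD -> full-band and sub-band mean
#' amplitude feature tables -> repeated-LASSO intersection and abnormal-region
#' calls -> the four-variant linear-SVM benchmark (chance, all features,
#' per-fold LASSO, intersection subset) with pairwise metric permutation
#' tests -> the per-subject phiC vs FC connectivity comparison. Deterministic
#' under a fixed `config$seed`; when `out_dir` is given all artifacts are
#' written (TSV/JSON) together with the configuration, seed and package
#' version for provenance, plus a JSON-lines log of stage events.
#'
#' @param cohort A `dmd_cohort`, or a directory path readable by
#'   [read_cohort()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param region_networks Optional named region -> network map.
#' @return A report list with elements `config`, `features_full`,
#'   `features_subband`, `selection`, `abnormal_report`, `metrics` (named
#'   list of `metric_set`s), `comparisons` (pairwise permutation results),
#'   `connectivity` (per-subject data frame), `log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         region_networks = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "dmd_cohort"))
  log <- list()
  note <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    log[[length(log) + 1]] <<- entry
    invisible(NULL)
  }
  stage_seeds <- derive_seeds(config$seed, 6L)

  note("features", mode = "full")
  feats_full <- withCallingHandlers(
    assemble_feature_table(cohort, mode = "full", band = config$band),
    warning = function(w) { note("warning", message = conditionMessage(w)) })
  feats_sub <- withCallingHandlers(
    assemble_feature_table(cohort, mode = "subband", k = config$k, band = config$band),
    warning = function(w) { note("warning", message = conditionMessage(w))
      invokeRestart("muffleWarning") })
  note("features", p_full = ncol(feats_full$values), p_subband = ncol(feats_sub$values))

  lcfg <- lasso_config(gamma = config$gamma, n_folds = config$n_folds,
                       n_repeats = config$n_repeats, seed = stage_seeds[1])
  sel <- withCallingHandlers(
    repeated_lasso_selection(feats_full, lcfg),
    warning = function(w) { note("warning", message = conditionMessage(w))
      invokeRestart("muffleWarning") })
  sel <- call_abnormal_regions(sel, feats_full, alpha = config$alpha,
                               B = config$B, seed = stage_seeds[2],
                               region_networks = region_networks)
  note("selection", intersection = length(sel$intersection),
       abnormal = length(sel$abnormal))

  variants <- c(chance = "chance", plain = "plain",
                per_fold_lasso = "per_fold_lasso")
  metrics <- list()
  for (nm in names(variants)) {
    metrics[[nm]] <- cross_validated_svm(feats_full, rounds = config$rounds,
                                         folds = config$folds,
                                         variant = variants[[nm]],
                                         gamma = config$gamma, C = config$C,
                                         seed = stage_seeds[3], name = nm)
  }
  if (length(sel$intersection) > 0) {
    metrics[["intersect"]] <- cross_validated_svm(
      feats_full, rounds = config$rounds, folds = config$folds,
      variant = "fixed_subset", subset = sel$intersection,
      C = config$C, seed = stage_seeds[3], name = "intersect")
  } else {
    note("warning", message = "empty intersection: intersect variant skipped")
  }
  pair_names <- utils::combn(names(metrics), 2, simplify = FALSE)
  comparisons <- lapply(pair_names, function(pr) {
    compare_feature_sets_permutation(metrics[[pr[1]]], metrics[[pr[2]]],
                                     B = config$B, seed = stage_seeds[4])
  })
  names(comparisons) <- vapply(pair_names, paste, collapse = "_vs_", FUN.VALUE = "")
  note("classification", variants = names(metrics))

  conn <- lapply(seq_along(cohort$subjects), function(i) {
    ts <- cohort$subjects[[i]]
    dec <- exact_dmd(build_snapshots(ts))
    fc <- functional_connectivity(ts)
    band_sub <- band_filter_modes(dec, config$band)
    res_band <- if (length(band_sub$indices) >= 2) {
      compare_connectivity(mode_sequence_correlation(dec, band_sub), fc)
    } else list(pearson_r = NA_real_, rmse = NA_real_)
    res_full <- compare_connectivity(mode_sequence_correlation(dec, all_modes(dec)), fc)
    data.frame(subject = i, n_modes_band = length(band_sub$indices),
               r_band = res_band$pearson_r, rmse_band = res_band$rmse,
               r_full = res_full$pearson_r, rmse_full = res_full$rmse)
  })
  conn <- do.call(rbind, conn)
  note("connectivity", mean_r_band = mean(conn$r_band, na.rm = TRUE),
       mean_r_full = mean(conn$r_full))

  report <- list(config = config, features_full = feats_full,
                 features_subband = feats_sub, selection = sel,
                 abnormal_report = sel$report, metrics = metrics,
                 comparisons = comparisons, connectivity = conn, log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(feats_full, file.path(out_dir, "features_full.tsv"))
    write_feature_table(feats_sub, file.path(out_dir, "features_subband.tsv"))
    write_selection_result(sel, file.path(out_dir, "selection"))
    for (nm in names(metrics)) {
      utils::write.table(metrics[[nm]], file.path(out_dir, sprintf("metrics_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      lapply(comparisons, function(cmp) {
        stats::setNames(as.list(cmp$p_value), cmp$metric)
      }),
      file.path(out_dir, "metric_comparisons.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(conn, file.path(out_dir, "connectivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("dmdbold"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
    writeLines(vapply(log, function(e) jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA),
                      FUN.VALUE = ""),
               file.path(out_dir, "pipeline_log.jsonl"))
  }
  report
}
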