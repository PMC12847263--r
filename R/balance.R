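#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square test of independence without continuity correction (1 degree of
#' freedom), as used for categorical group-balance checks (e.g. sex or
#' handedness counts between patients and controls).
#'
#' @param table 2x2 matrix of nonnegative integer counts with all row and
#'   column margins positive.
#' @return List with `statistic`, `p_value`, `df = 1`.
#' @examples
#' chi_square_2x2(matrix(c(48, 20, 54, 14), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2, 2)), "`table` must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "counts must be nonnegative integers")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "all margins must be positive")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, df = 1L)
}

#' Welch two-sample t-test
#'
#' Two-sided Welch (unequal-variance) t-test for a continuous group-balance
#' covariate such as age.
#'
#' @param a,b Numeric samples, each of size >= 2; at least one must have
#'   positive variance.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
welch_t_test <- function(a, b) {
  assert_that(length(a) >= 2 && length(b) >= 2, "both samples need size >= 2")
  assert_that(stats::var(a) > 0 || stats::var(b) > 0,
              "zero variance in both samples: t-test undefined")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Cohort balance report
#'
#' Tests each covariate for a group difference: Welch t-test for continuous
#' covariates, 2x2 chi-square (no continuity correction) for categorical
#' count tables.
#'
#' @param continuous Named list; each element a list of two numeric vectors
#'   (group 0, group 1).
#' @param tables Named list of 2x2 count matrices (rows = groups).
#' @return Data frame with `covariate`, `test`, `statistic`, `p_value`.
#' @export
balance_report <- function(continuous = list(), tables = list()) {
  rows <- list()
  for (nm in names(continuous)) {
    ht <- welch_t_test(continuous[[nm]][[1]], continuous[[nm]][[2]])
    rows[[length(rows) + 1]] <- data.frame(covariate = nm, test = "welch_t",
                                           statistic = ht$statistic,
                                           p_value = ht$p_value)
  }
  for (nm in names(tables)) {
    ht <- chi_square_2x2(tables[[nm]])
    rows[[length(rows) + 1]] <- data.frame(covariate = nm, test = "chi_square",
                                           statistic = ht$statistic,
                                           p_value = ht$p_value)
  }
  do.call(rbind, rows)
}
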