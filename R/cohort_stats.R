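#' Summary of a quantitative variable
#'
#' Median with interquartile range (default) or mean with standard
#' deviation.  Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7); the same convention is used by the
#' synthetic-cohort calibration targets.
#'
#' @param values non-empty numeric vector (missing values dropped).
#' @param method \code{"median_iqr"} or \code{"mean_sd"}.
#' @return A named list: \code{n} plus \code{median}, \code{q1}, \code{q3}
#'   or \code{mean}, \code{sd}.
#' @export
#' @examples
#' summarize_numeric(1:8)
summarize_numeric <- function(values, method = c("median_iqr", "mean_sd")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop_invalid("'values' must be non-empty")
  check_number(values, "values")
  if (method == "median_iqr") {
    q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
  } else {
    list(n = length(values), mean = mean(values), sd = stats::sd(values))
  }
}

new_group_comparison <- function(variable_name, groups, summaries, test_name,
                                 statistic, p_value) {
  structure(list(variable_name = variable_name, groups = groups,
                 summaries = summaries, test_name = test_name,
                 statistic = statistic, p_value = p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s: %s, statistic = %s, p = %.4g\n",
              x$variable_name, paste(x$groups, collapse = "/"), x$test_name,
              ifelse(is.na(x$statistic), "NA", format(x$statistic, digits = 4)),
              x$p_value))
  invisible(x)
}

#' Compare a quantitative variable across groups (Kruskal-Wallis)
#'
#' Nonparametric comparison of a quantitative variable across two or more
#' groups using the Kruskal-Wallis rank-sum test with tie correction
#' (\code{stats::kruskal.test}); p-value from the chi-square distribution
#' with k-1 degrees of freedom.
#'
#' @param values numeric vector.
#' @param group group labels, same length; every group must be non-empty.
#' @param variable_name label carried into the result.
#' @return A \code{"group_comparison"} with per-group median/IQR summaries.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
compare_groups <- function(values, group, variable_name = "value") {
  check_number(values, "values", allow_na = TRUE)
  if (length(values) != length(group)) {
    stop_invalid("'values' and 'group' must have the same length")
  }
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- factor(group[keep])
  if (nlevels(group) < 2) stop_invalid("need at least two groups")
  if (any(tabulate(group, nlevels(group)) == 0)) {
    stop_invalid("every group must be non-empty")
  }
  kt <- stats::kruskal.test(values, group)
  summaries <- lapply(split(values, group), summarize_numeric)
  new_group_comparison(variable_name, levels(group), summaries,
                       "kruskal_wallis", unname(kt$statistic), kt$p.value)
}

#' Compare a categorical variable across groups (chi-square / Fisher)
#'
#' Pearson chi-square test without continuity correction when every expected
#' count is at least 5; otherwise Fisher's exact test for 2x2 tables (two-
#' sided p as the sum of the probabilities of all tables as or more extreme
#' than the observed one) or, for larger sparse tables, the chi-square test
#' with a warning.  The test actually used is reported in the result.
#'
#' @param counts matrix (at least 2x2) of non-negative integer counts; rows
#'   are variable categories, columns are groups.
#' @param variable_name label carried into the result.
#' @return A \code{"group_comparison"}; \code{statistic} is the chi-square
#'   statistic or \code{NA} for Fisher's exact test.
#' @export
#' @examples
#' compare_categorical(matrix(c(8, 1, 2, 9), 2))
compare_categorical <- function(counts, variable_name = "value") {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_invalid("'counts' must be at least 2x2")
  }
  check_number(as.vector(counts), "counts", 0, Inf, integer = TRUE)
  n <- sum(counts)
  if (n == 0) stop_invalid("'counts' must contain at least one observation")
  expected <- outer(rowSums(counts), colSums(counts)) / n
  groups <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
  summaries <- lapply(seq_len(ncol(counts)), function(j) {
    list(counts = unname(counts[, j]), percent = 100 * counts[, j] / sum(counts[, j]))
  })
  names(summaries) <- groups
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(counts, correct = FALSE)
    new_group_comparison(variable_name, groups, summaries, "chi_square",
                         unname(ct$statistic), ct$p.value)
  } else if (nrow(counts) == 2 && ncol(counts) == 2) {
    ft <- stats::fisher.test(counts)
    new_group_comparison(variable_name, groups, summaries, "fisher_exact",
                         NA_real_, ft$p.value)
  } else {
    warning("expected count below 5 in a table larger than 2x2; ",
            "falling back to the chi-square test")
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    new_group_comparison(variable_name, groups, summaries, "chi_square",
                         unname(ct$statistic), ct$p.value)
  }
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties; the p-value uses the
#' t-approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of
#' freedom (the large-sample approximation of \code{stats::cor.test}).
#' A constant input vector has no rank ordering; rho is returned as
#' \code{NA} with a warning.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return A list with \code{rho}, \code{p_value} and \code{n}.
#' @export
#' @examples
#' spearman_correlation(1:5, c(2, 1, 4, 3, 5))
spearman_correlation <- function(x, y) {
  check_number(x, "x")
  check_number(y, "y")
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have the same length")
  if (length(x) < 3) stop_invalid("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input vector; Spearman correlation is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
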