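#' Summarize a variable within a group
#'
#' Mean and standard error of the mean (sample SD with n-1 denominator
#' divided by sqrt(n)), the convention used for all reported group values.
#'
#' @param values numeric vector (NAs dropped).
#' @param label group label.
#' @param variable variable name carried into reports.
#' @return object of class \code{group_summary}: list with group,
#'   variable, n, mean, sem (NA when n < 2), values.
#' @export
summarize_group <- function(values, label = NA_character_,
                            variable = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values")
  n <- length(values)
  structure(list(group = label, variable = variable, n = n,
                 mean = mean(values),
                 sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
                 values = values),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s %s: %.4g +/- %.4g (n = %d, mean +/- SEM)\n",
              x$group, x$variable, x$mean, x$sem, x$n))
  invisible(x)
}

#' Two-sided Mann-Whitney U comparison of two independent groups
#'
#' Exact p-value when the combined sample size is at most
#' \code{exact_max} and the data are tie-free; normal approximation with
#' tie correction otherwise (the standard rank-sum machinery of
#' \code{stats::wilcox.test}).
#'
#' @param group1,group2 numeric vectors.
#' @param variable name for reporting.
#' @param family number of comparisons in the Bonferroni family (default
#'   1: no correction).
#' @param exact_max largest combined n for which the exact distribution is
#'   used.
#' @return object of class \code{comparison_result}: list with variable,
#'   test, statistic (U for group1), p_raw, p_adjusted, family, method.
#' @export
mann_whitney <- function(group1, group2, variable = NA_character_,
                         family = 1L, exact_max = 20L) {
  if (length(group1) < 1 || length(group2) < 1) stop("both groups must be non-empty")
  n <- length(group1) + length(group2)
  ties <- anyDuplicated(c(group1, group2)) > 0
  use_exact <- n <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = use_exact, correct = !use_exact)
  )
  structure(list(variable = variable, test = "Mann-Whitney U",
                 statistic = unname(wt$statistic),
                 p_raw = wt$p.value,
                 p_adjusted = bonferroni(wt$p.value, family),
                 family = family,
                 method = if (use_exact) "exact"
                          else "normal approximation, tie-corrected"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s (%s): U = %g, raw p = %.4g, adjusted p = %.4g (family %d, %s)\n",
              x$test, x$variable, x$statistic, x$p_raw, x$p_adjusted,
              x$family, x$method))
  invisible(x)
}

#' Bonferroni correction
#'
#' Each p-value is multiplied by the family size and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param family family size; defaults to \code{length(p)}.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, family = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (family < 1) stop("family size must be >= 1")
  pmin(1, p * family)
}
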